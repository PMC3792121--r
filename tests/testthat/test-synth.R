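test_that("generators are deterministic under a fixed seed", {
  expect_identical(
    make_random_web(seed = 4)$groups, make_random_web(seed = 4)$groups
  )
  expect_identical(
    make_block_series(seed = 6), make_block_series(seed = 6)
  )
  b1 <- make_forcing_scenario(c(pp = 1), noise_sd = 0.1, seed = 2)
  b2 <- make_forcing_scenario(c(pp = 1), noise_sd = 0.1, seed = 2)
  expect_identical(b1, b2)
  # generators do not disturb the caller's RNG stream
  set.seed(123)
  before <- stats::rnorm(1)
  set.seed(123)
  invisible(make_random_web(seed = 9))
  expect_identical(stats::rnorm(1), before)
})

test_that("every generated web is balanced with EE in [0, 1]", {
  for (seed in 1:10) {
    web <- make_random_web(
      n_groups = 8 + seed %% 5, n_producers = 1 + seed %% 2,
      n_detritus = 1 + seed %% 2, connectance = 0.2 + 0.05 * (seed %% 4),
      seed = seed
    )
    ee <- web$groups$EE[web$groups$role != "detritus"]
    expect_true(all(ee >= 0 & ee <= 1))
    bal <- check_mass_balance(web)
    expect_lt(max(abs(bal$residual)), 1e-9 * max(bal$production))
  }
})

test_that("the Baltic-like fixture has the documented structure", {
  fx <- make_baltic_fixture()
  web <- fx$web
  expect_equal(nrow(web$groups), 21)
  expect_equal(sum(web$groups$role == "detritus"), 2)
  expect_equal(sort(web$fleets), c("cod", "herring", "sprat"))
  expect_true(all(
    web$groups$EE[web$groups$role != "detritus"] >= 0 &
      web$groups$EE[web$groups$role != "detritus"] <= 1
  ))
  expect_equal(nrow(fx$params$stanza_links), 5)
  # bit-stable: fixture construction is seed-free
  expect_identical(web$groups, make_baltic_fixture()$web$groups)
  # the fixture network has 21 compartments + 3 boundary nodes
  net <- to_flow_network(web)
  expect_equal(dim(net$T), c(24, 24))
})

test_that("forcing scenarios plant exact steps when noiseless", {
  f <- make_forcing_scenario(
    c(pp = 1, F_x = 0.4),
    years = 1974:2006,
    shifts = tibble::tibble(series = "F_x", year = 1988, factor = 2),
    noise_sd = 0
  )
  expect_equal(unique(f$F_x[f$year < 1988]), 0.4)
  expect_equal(unique(f$F_x[f$year >= 1988]), 0.8)
  expect_equal(unique(f$pp), 1)
  # planted step recovered by stars on the noiseless series
  expect_equal(shift_years(stars(f$F_x, years = f$year)), 1988)
})

test_that("AR(1) noise has the requested lag-1 autocorrelation", {
  f <- make_forcing_scenario(
    c(pp = 1), years = 1:500, noise_sd = 0.2, ar1 = 0.6, seed = 12
  )
  eps <- f$pp - 1
  r1 <- stats::acf(eps, plot = FALSE)$acf[2]
  se <- sqrt(1 / 500) * 3
  expect_lt(abs(r1 - 0.6), se + 0.05)
})

test_that("block series separate along PC1 by construction", {
  d <- make_block_series(mean_shift = 5, noise_sd = 1, seed = 21)
  p <- pca_index(d)
  s1 <- p$scores$PC1[1:10]
  s2 <- p$scores$PC1[11:20]
  expect_true(all(sign(s1) == sign(s1[1])))
  expect_true(all(sign(s2) == -sign(s1[1])))
})
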