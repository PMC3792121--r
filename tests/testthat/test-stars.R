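test_that("a constant series yields no shifts", {
  res <- stars(rep(5, 30))
  expect_equal(nrow(res$shifts), 0)
  expect_equal(nrow(res$regimes), 1)
})

test_that("a clean step is flagged at the step year", {
  with_local_seed(42, {
    x <- c(rep(0, 15), rep(10, 15)) + stats::rnorm(30, 0, 0.1)
  })
  res <- stars(x, alpha = 0.05, cutoff = 5, huber = 3)
  confirmed <- res$shifts[!res$shifts$end_truncated, ]
  expect_equal(confirmed$year, 16)
  expect_equal(confirmed$direction, "up")
  expect_gt(confirmed$rsi, 0)
  # regime means bracket the step
  expect_lt(res$regimes$weighted_mean[1], 1)
  expect_gt(res$regimes$weighted_mean[2], 9)
})

test_that("shifts only confirmable in the last cutoff years are flagged", {
  x <- c(rep(0, 30), rep(10, 3))
  res <- stars(x, cutoff = 5)
  expect_true(all(res$shifts$end_truncated))
  expect_length(shift_years(res), 0)
  expect_length(shift_years(res, include_truncated = TRUE), 1)
})

test_that("a lone outlier is Huber-downweighted, not a regime", {
  with_local_seed(7, {
    x <- stats::rnorm(30, 0, 0.5)
  })
  x[15] <- 12 # single spike
  res <- stars(x, alpha = 0.05, cutoff = 5, huber = 3)
  expect_length(shift_years(res), 0)
  # the spike barely moves the weighted regime mean
  expect_lt(abs(res$regimes$weighted_mean[1] - mean(x[-15])), 0.5)
})

test_that("stars recovers a 3-SD step within +/- 1 year in most seeds", {
  hits <- 0
  n_seeds <- 1000
  for (seed in seq_len(n_seeds)) {
    x <- with_local_seed(seed, c(rep(0, 15), rep(3, 18)) + stats::rnorm(33))
    yrs <- shift_years(stars(x, alpha = 0.05, cutoff = 5, huber = 3))
    if (any(abs(yrs - 16) <= 1)) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("white-noise false-shift rate stays near the nominal level", {
  false_series <- 0
  n_seeds <- 1000
  for (seed in seq_len(n_seeds)) {
    x <- with_local_seed(seed + 5000, stats::rnorm(33))
    if (length(shift_years(stars(x, alpha = 0.05, cutoff = 5, huber = 3))) > 0) {
      false_series <- false_series + 1
    }
  }
  expect_lte(false_series / n_seeds, 2 * 0.05)
})

test_that("series shorter than two cutoffs are rejected", {
  expect_error(stars(rnorm(9), cutoff = 5), "at least")
  expect_error(stars(c(rnorm(20), NA)), "missing")
})

test_that("detect_shifts maps stars over table columns", {
  d <- tibble::tibble(
    year = 1974:2006,
    flat = 1,
    step = c(rep(0, 15), rep(5, 18))
  )
  out <- detect_shifts(d)
  expect_true(all(out$series == "step"))
  expect_equal(out$year[!out$end_truncated], 1989) # 15th year is 1988
})

test_that("coefficient of variation follows the sample formula", {
  d <- tibble::tibble(year = 1:10, a = rep(4, 10), b = 1:10)
  cv <- cv_by_period(d, list(c(1, 10)))
  expect_equal(cv$cv[cv$series == "a"], 0)
  expect_equal(
    cv$cv[cv$series == "b"], stats::sd(1:10) / mean(1:10)
  )
  # {1, 3} -> sd/mean = sqrt(2)/2
  d2 <- tibble::tibble(year = 1:2, x = c(1, 3))
  expect_equal(cv_by_period(d2, list(c(1, 2)))$cv, sqrt(2) / 2)
  # invariant under positive rescaling
  d3 <- tibble::tibble(year = 1:6, x = rlnorm(6))
  expect_equal(
    cv_by_period(d3, list(c(1, 6)))$cv,
    cv_by_period(dplyr::mutate(d3, x = 7 * x), list(c(1, 6)))$cv
  )
  # zero mean -> explicit missing value
  d4 <- tibble::tibble(year = 1:4, x = c(-1, 1, -1, 1))
  expect_true(is.na(cv_by_period(d4, list(c(1, 4)))$cv))
  # period outside the span -> error
  expect_error(cv_by_period(d, list(c(0, 10))), "outside")
})

test_that("anomalies follow the chosen reference", {
  d <- tibble::tibble(year = 1:5, x = c(2, 4, 6, 8, 10))
  a1 <- anomaly_series(d, "initial")
  expect_equal(a1$x[1], 0)
  expect_equal(diff(a1$x), diff(d$x)) # linear stays linear
  a2 <- anomaly_series(d, "mean")
  expect_equal(sum(a2$x), 0)
})
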