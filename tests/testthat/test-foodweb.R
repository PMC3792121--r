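test_that("mass balance residuals match hand arithmetic", {
  # predation = 1 * 50 * 1 = 50 = B*PB*EE = 10*10*0.5 -> residual 0
  bal <- check_mass_balance(toy_web())
  expect_equal(bal$residual[bal$group == "algae"], 0)

  # consumer QB = 60 -> predation 60 vs production allocated 50: residual -10
  # (allocated - B*PB*EE = 60 - 50... sign: residual = allocated - production term)
  bal2 <- check_mass_balance(toy_web(cons_QB = 60))
  expect_equal(bal2$residual[bal2$group == "algae"], 10)

  # nothing consumed, nothing caught, EE = 0 -> all residuals 0
  web0 <- food_web(
    groups = tibble::tibble(
      name = c("p1", "p2", "det"),
      role = c("producer", "producer", "detritus"),
      B = c(5, 3, 1), PB = c(10, 20, 0), QB = 0,
      EE = c(0, 0, NA), GS = 0
    )
  )
  expect_equal(check_mass_balance(web0)$residual, c(0, 0))
})

test_that("unknown EE triggers an explicit error, not a silent zero", {
  web <- toy_web()
  web$groups$EE[1] <- NA
  expect_error(check_mass_balance(web), "EE unknown.*algae")
})

test_that("solve_missing_ee recovers EE and flags unbalanced webs", {
  web <- toy_web()
  web$groups$EE <- NA_real_
  solved <- solve_missing_ee(web)
  expect_equal(solved$groups$EE[1], 0.5) # 50 / (10*10)
  expect_equal(solved$groups$EE[2], 0) # uneaten, uncaught

  # predation 110 > production 100 -> EE would exceed 1
  over <- toy_web(cons_QB = 110)
  over$groups$EE <- NA_real_
  expect_error(solve_missing_ee(over), "unbalanced.*algae")
})

test_that("trophic levels solve the diet linear system", {
  tl <- trophic_levels(chain_web())
  expect_equal(tl$TL, c(1, 2, 2.5, 1))
})

test_that("import diet counts as trophic level 1 food", {
  web <- food_web(
    groups = tibble::tibble(
      name = c("algae", "mixed", "det"),
      role = c("producer", "consumer", "detritus"),
      B = c(10, 1, 5), PB = c(10, 4, 0), QB = c(0, 20, 0),
      EE = c(0.5, 0, NA), GS = c(0, 0.2, 0)
    ),
    diet = tibble::tibble(
      predator = "mixed", prey = c("algae", "import"), proportion = c(0.5, 0.5)
    )
  )
  # TL = 1 + 0.5*1 + 0.5*1 = 2
  expect_equal(trophic_levels(web)$TL[2], 2)
})

test_that("trophic levels agree with the power-iteration oracle", {
  for (seed in 1:5) {
    web <- make_random_web(n_groups = 12, seed = seed)
    expect_equal(trophic_levels(web)$TL, tl_power_oracle(web),
      tolerance = 1e-10
    )
  }
})

test_that("flow network bookkeeping follows Ecopath identities", {
  # consumer respiration = (1 - GS) * Q - P = 0.8*50 - 10 = 30
  net <- to_flow_network(toy_web())
  n <- net$n
  expect_equal(net$T["grazer", "respiration"], 30)
  # unassimilated food: GS * Q = 10 into detritus
  expect_equal(net$T["grazer", "det"], 0.2 * 50 + (1 - 0) * 1 * 10)
  # producer import = primary production
  expect_equal(net$T["import", "algae"], 10 * 10)
  # no fleets: export column only holds the detritus-balancing term
  expect_equal(sum(net$T[seq_len(n), "export"][net$role != "detritus"]), 0)
})

test_that("balanced webs give balanced networks (round trip)", {
  for (seed in 1:5) {
    web <- make_random_web(n_groups = 10, n_detritus = 2, seed = seed)
    net <- to_flow_network(web)
    tst <- total_system_throughput(net)
    expect_lt(max(abs(compartment_imbalance(net))), 1e-6 * tst)
  }
})

test_that("solve_missing_ee then check_mass_balance gives zero residuals", {
  for (seed in 1:5) {
    web <- make_random_web(n_groups = 9, seed = seed + 10)
    bal <- check_mass_balance(web)
    expect_lt(max(abs(bal$residual)), 1e-10 * max(bal$production))
  }
})

test_that("negative respiration is floored with a warning", {
  # PB = 45 > (1-GS)*QB = 40: assimilation cannot cover production
  w <- capture_warnings(
    net <- to_flow_network(toy_web(cons_PB = 45, cons_EE = 0))
  )
  expect_match(w, "floored", all = FALSE)
  expect_equal(net$T["grazer", "respiration"], 0)
})

test_that("food_web validates its invariants", {
  g <- tibble::tibble(
    name = c("a", "b", "det"), role = c("producer", "consumer", "detritus"),
    B = 1, PB = 1, QB = c(0, 10, 0), EE = c(0, 0, NA), GS = 0
  )
  # diet not summing to 1
  expect_error(
    food_web(g, tibble::tibble(predator = "b", prey = "a", proportion = 0.6)),
    "sum to 1"
  )
  # unknown prey
  expect_error(
    food_web(g, tibble::tibble(predator = "b", prey = "zz", proportion = 1)),
    "unknown prey"
  )
  # consumer without QB
  g2 <- g
  g2$QB[2] <- 0
  expect_error(
    food_web(g2, tibble::tibble(predator = "b", prey = "a", proportion = 1)),
    "QB > 0"
  )
  # missing detritus
  g3 <- g[1:2, ]
  expect_error(
    food_web(g3, tibble::tibble(predator = "b", prey = "a", proportion = 1)),
    "detritus"
  )
})
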