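test_that("TST sums every flow including boundaries", {
  net <- net_from_edges(
    tibble::tibble(from = "c1", to = "c2", flow = 7),
    role = c("consumer", "consumer", "detritus")
  )
  expect_equal(total_system_throughput(net), 7)

  # 3-compartment chain: import 10 -> A; A -> B 6; B -> export 2;
  # A -> resp 4; B -> resp 4
  chain <- net_from_edges(
    tibble::tibble(
      from = c("import", "c1", "c2", "c1", "c2"),
      to = c("c1", "c2", "export", "respiration", "respiration"),
      flow = c(10, 6, 2, 4, 4)
    ),
    role = c("consumer", "consumer", "detritus")
  )
  expect_equal(total_system_throughput(chain), 10 + 6 + 2 + 4 + 4)

  empty <- net_from_edges(
    tibble::tibble(from = character(), to = character(), flow = numeric()),
    role = c("consumer", "detritus")
  )
  expect_equal(total_system_throughput(empty), 0)
})

test_that("two disjoint equal flows carry exactly 1 bit of AMI", {
  net <- net_from_edges(
    tibble::tibble(from = c("c1", "c2"), to = c("c3", "c4"), flow = c(5, 5)),
    role = c(rep("consumer", 4), "detritus")
  )
  info <- information_decomposition(net)
  expect_equal(info$AMI, 1)
  expect_equal(info$H, 1)
})

test_that("a single internal flow has zero AMI and zero redundancy", {
  net <- net_from_edges(
    tibble::tibble(from = "c1", to = "c2", flow = 3),
    role = c("consumer", "consumer", "detritus")
  )
  info <- information_decomposition(net)
  expect_equal(info$AMI, 0)
  expect_equal(info$R, 0)
})

test_that("ascendancy plus total overhead equals capacity on random webs", {
  for (seed in 1:8) {
    net <- to_flow_network(make_random_web(n_groups = 11, seed = seed))
    info <- information_decomposition(net)
    T <- net$T
    tst <- sum(T)
    # total overhead from its own definition, independent of A and C
    pos <- which(T > 0, arr.ind = TRUE)
    f <- T[pos]
    ov <- -sum(f * log2(f^2 / (rowSums(T)[pos[, 1]] * colSums(T)[pos[, 2]])))
    expect_equal(info$A + ov, info$C, tolerance = 1e-9)
    expect_lte(info$AMI, info$H)
    expect_gte(info$AC_ratio, 0)
    expect_lte(info$AC_ratio, 1)
    expect_lte(info$R, ov * (1 + 1e-12))
  }
})

test_that("acyclic networks have zero cycling", {
  chain <- net_from_edges(
    tibble::tibble(
      from = c("import", "c1", "c2"),
      to = c("c1", "c2", "export"),
      flow = c(5, 5, 5)
    ),
    role = c("consumer", "consumer", "detritus")
  )
  expect_equal(finn_cycle_index(chain), 0)
})

test_that("cycling matches the truncated path-enumeration oracle", {
  loop <- net_from_edges(
    tibble::tibble(
      from = c("import", "c1", "c2", "c2"),
      to = c("c1", "c2", "c1", "export"),
      flow = c(5, 10, 5, 5)
    ),
    role = c("consumer", "consumer", "detritus")
  )
  expect_equal(
    finn_cycle_index(loop), fci_path_oracle(loop),
    tolerance = 1e-6
  )

  # random small networks (<= 6 compartments) against the oracle
  for (seed in 1:6) {
    web <- make_random_web(
      n_groups = 6, n_producers = 1, n_detritus = 1,
      connectance = 0.5, seed = seed
    )
    net <- to_flow_network(web)
    expect_equal(
      finn_cycle_index(net), fci_path_oracle(net),
      tolerance = 1e-6
    )
    expect_equal(
      finn_cycle_index(net, include_detritus = FALSE),
      fci_path_oracle(net, include_detritus = FALSE),
      tolerance = 1e-6
    )
  }
})

test_that("a cycle through detritus counts for FCI but not PCI", {
  # c1 -> det -> c1 loop (detritivory)
  net <- net_from_edges(
    tibble::tibble(
      from = c("import", "c1", "det", "c1"),
      to = c("c1", "det", "c1", "export"),
      flow = c(5, 10, 5, 5)
    ),
    role = c("consumer", "detritus"), labels = c("c1", "det")
  )
  expect_gt(finn_cycle_index(net), 0)
  expect_equal(finn_cycle_index(net, include_detritus = FALSE), 0)
})

test_that("mean path length follows Finn's convention", {
  net <- net_from_edges(
    tibble::tibble(
      from = c("import", "c1"), to = c("c1", "export"), flow = c(10, 10)
    ),
    role = c("consumer", "detritus")
  )
  expect_equal(mean_path_length(net), 2)

  # a chain of k internal transfers: TST = 10*(k+2), MPL = k + 2
  k <- 4
  edges <- tibble::tibble(
    from = c("import", paste0("c", 1:k), paste0("c", k + 1)),
    to = c(paste0("c", 1:(k + 1)), "export"),
    flow = 10
  )
  chain <- net_from_edges(edges, role = c(rep("consumer", k + 1), "detritus"))
  expect_equal(mean_path_length(chain), k + 2)

  # adding an internal transfer increases MPL
  more <- net_from_edges(
    tibble::tibble(
      from = c("import", "c1", "c1", "c2"),
      to = c("c1", "export", "c2", "export"),
      flow = c(10, 5, 5, 5)
    ),
    role = c("consumer", "consumer", "detritus")
  )
  expect_gt(mean_path_length(more), 2)
})

test_that("proportional flow to detritus is the detrital inflow share", {
  none <- net_from_edges(
    tibble::tibble(
      from = c("import", "c1"), to = c("c1", "export"), flow = c(5, 5)
    ),
    role = c("consumer", "detritus")
  )
  expect_equal(flow_to_detritus_fraction(none), 0)

  net <- to_flow_network(toy_web())
  det_in <- sum(net$T[, "det"])
  expect_equal(
    flow_to_detritus_fraction(net),
    det_in / total_system_throughput(net)
  )
})

test_that("ecosystem ratios match hand bookkeeping on the toy web", {
  net <- to_flow_network(toy_web())
  r <- ecosystem_ratios(net)
  # TPP = 10*10; TR = consumer respiration 30
  expect_equal(r$TPP_TR, 100 / 30)
  # ToTP = 100 + 10; ToTB = 10 + 1 (living only)
  expect_equal(r$ToTP_ToTB, 110 / 11)
  expect_equal(r$TotC, 0) # no fleets
})

test_that("fisheries indices: mTLc and single-path PPR closed form", {
  # catch 1 t/km2/yr of a pure herbivore with g = PB/QB = 0.2
  web <- food_web(
    groups = tibble::tibble(
      name = c("algae", "herb", "det"),
      role = c("producer", "consumer", "detritus"),
      B = c(100, 5, 10), PB = c(10, 4, 0), QB = c(0, 20, 0),
      EE = NA_real_, GS = c(0, 0.2, 0)
    ),
    diet = tibble::tibble(predator = "herb", prey = "algae", proportion = 1),
    landings = tibble::tibble(group = "herb", fleet = "f1", landings = 1)
  )
  web <- solve_missing_ee(web)
  net <- to_flow_network(web)
  fi <- fisheries_indices(net)
  expect_equal(fi$mTLc, 2) # only the TL-2 herbivore is caught
  # PPR = Y / g = 1 / 0.2 = 5 units of producer production; PP = 1000
  expect_equal(fi$PPR_PP, 5 / 1000)
})

test_that("mTLc averages trophic levels weighted by catch", {
  net <- to_flow_network(chain_web())
  tl <- trophic_levels_flow(net)
  # equal synthetic catches at TL 2 and 2.5 -> mean 2.25
  net$catch <- c(0, 1, 1, 0)
  fi <- fisheries_indices(net, tl)
  expect_equal(fi$mTLc, 2.25)
  # zero catch -> explicit missing value
  net$catch <- rep(0, 4)
  expect_true(is.na(fisheries_indices(net, tl)$mTLc))
})

test_that("Kempton Q follows the inter-quartile dominance-curve formula", {
  # geometric biomass sequence: b[k] = 100 * 0.5^(k-1), S = 8
  b <- 100 * 0.5^(0:7)
  tl <- rep(4, 8)
  s <- 8
  i25 <- ceiling(0.25 * s)
  i75 <- ceiling(0.75 * s)
  expected <- (s / 2) / log10(b[i25] / b[i75])
  expect_equal(kempton_q(b, tl), expected)
  # scale invariance
  expect_equal(kempton_q(2 * b, tl), kempton_q(b, tl))
  # more even biomasses -> larger Q (brute-force comparison)
  even <- 100 * 0.9^(0:7)
  expect_gt(kempton_q(even, tl), kempton_q(b, tl))
  # below-threshold groups excluded; < 2 eligible -> NA
  expect_true(is.na(kempton_q(b, c(4, rep(2, 7)))))
})

test_that("the indicator set assembles all fifteen indicators", {
  fx <- make_baltic_fixture()
  net <- to_flow_network(fx$web)
  ind <- ena_indicators(net, year = 1974)
  fifteen <- c(
    "TST", "AC_ratio", "R", "AMI", "H", "MPL", "KemptonQ", "FCI", "PCI",
    "PFD", "ToTP_ToTB", "TPP_TR", "PPR_PP", "mTLc", "TotC"
  )
  expect_true(all(fifteen %in% names(ind)))
  expect_true(all(!is.na(ind[fifteen])))
  # composition: each field equals its individual-operation value
  expect_equal(ind$TST, total_system_throughput(net))
  expect_equal(ind$FCI, finn_cycle_index(net))
  expect_equal(ind$MPL, mean_path_length(net))
  info <- information_decomposition(net)
  expect_equal(ind$R_pct_C, info$R_pct_C)
})

test_that("indices are invariant under compartment reordering", {
  web <- make_random_web(n_groups = 10, n_detritus = 2, seed = 3)
  net <- to_flow_network(web)
  n <- net$n
  perm <- c(sample(seq_len(n)), n + 1L, n + 2L, n + 3L)
  net2 <- flow_network(
    T = net$T[perm, perm], labels = net$labels[perm],
    role = net$role[perm[seq_len(n)]],
    biomass = net$biomass[perm[seq_len(n)]],
    production = net$production[perm[seq_len(n)]],
    catch = net$catch[perm[seq_len(n)]],
    quiet = TRUE
  )
  a <- ena_indicators(net)
  b <- ena_indicators(net2)
  for (v in setdiff(names(a), "year")) {
    expect_equal(a[[v]], b[[v]], tolerance = 1e-9, label = v)
  }
})

test_that("collapsing a redundant parallel flow never increases redundancy", {
  # c1 feeds c2 and c3 in parallel vs the same total through one channel
  par <- net_from_edges(
    tibble::tibble(
      from = c("import", "c1", "c1", "c2", "c3"),
      to = c("c1", "c2", "c3", "export", "export"),
      flow = c(10, 5, 5, 5, 5)
    ),
    role = c(rep("consumer", 3), "detritus")
  )
  ser <- net_from_edges(
    tibble::tibble(
      from = c("import", "c1", "c2", "c3"),
      to = c("c1", "c2", "export", "export"),
      flow = c(10, 10, 10, 0)
    ),
    role = c(rep("consumer", 3), "detritus")
  )
  expect_gte(
    information_decomposition(par)$R,
    information_decomposition(ser)$R
  )
})
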