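# small hand-checkable webs used across the suite

# 1 producer eaten by 1 consumer, plus an (inert) detritus pool:
# predation on producer = 1 * 50 * 1 = 50 = 10 * 10 * 0.5
toy_web <- function(cons_QB = 50, cons_PB = 10, prod_EE = 0.5,
                    cons_EE = 0, GS = 0.2) {
  food_web(
    groups = tibble::tibble(
      name = c("algae", "grazer", "det"),
      role = c("producer", "consumer", "detritus"),
      B = c(10, 1, 5),
      PB = c(10, cons_PB, 0),
      QB = c(0, cons_QB, 0),
      EE = c(prod_EE, cons_EE, NA),
      GS = c(0, GS, 0)
    ),
    diet = tibble::tibble(predator = "grazer", prey = "algae", proportion = 1)
  )
}

# producer -> herbivore -> predator chain; predator eats 50% herbivore,
# 50% producer, so TL = (1, 2, 2.5, 1)
chain_web <- function() {
  web <- food_web(
    groups = tibble::tibble(
      name = c("algae", "herb", "pred", "det"),
      role = c("producer", "consumer", "consumer", "detritus"),
      B = c(50, 5, 0.5, 10),
      PB = c(20, 8, 1.5, 0),
      QB = c(0, 40, 6, 0),
      EE = c(NA, NA, NA, NA),
      GS = c(0, 0.2, 0.2, 0)
    ),
    diet = tibble::tibble(
      predator = c("herb", "pred", "pred"),
      prey = c("algae", "herb", "algae"),
      proportion = c(1, 0.5, 0.5)
    )
  )
  solve_missing_ee(web)
}

# build a flow network directly from an edge list; boundary nodes are
# addressed by the names "import", "export", "respiration"
net_from_edges <- function(edges, role, labels = NULL, ...) {
  n <- length(role)
  if (is.null(labels)) labels <- paste0("c", seq_len(n))
  all_labs <- c(labels, "import", "export", "respiration")
  T <- matrix(0, n + 3, n + 3, dimnames = list(all_labs, all_labs))
  for (r in seq_len(nrow(edges))) {
    T[edges$from[r], edges$to[r]] <- edges$flow[r]
  }
  flow_network(T = T, labels = all_labs, role = role, quiet = TRUE, ...)
}

# independent truncated path-enumeration oracle for the cycling index:
# N_ii = sum_k (G^k)_ii with G the input-fraction matrix, truncated at
# path length `kmax`
fci_path_oracle <- function(net, kmax = 50, include_detritus = TRUE) {
  n <- net$n
  keep <- seq_len(n)
  if (!include_detritus) keep <- keep[net$role != "detritus"]
  idx <- c(keep, n + 1L, n + 2L, n + 3L)
  T <- net$T[idx, idx, drop = FALSE]
  m <- length(keep)
  inflow <- colSums(T[seq_len(m + 1), seq_len(m), drop = FALSE])
  G <- T[seq_len(m), seq_len(m), drop = FALSE]
  pos <- inflow > 0
  G[, pos] <- sweep(G[, pos, drop = FALSE], 2, inflow[pos], `/`)
  G[, !pos] <- 0
  Ndiag <- rep(1, m)
  P <- diag(m)
  for (k in seq_len(kmax)) {
    P <- P %*% G
    Ndiag <- Ndiag + diag(P)
  }
  cycled <- ifelse(Ndiag > 0, (Ndiag - 1) / Ndiag * inflow, 0)
  sum(cycled) / sum(T)
}

# power-iteration oracle for trophic levels: TL <- 1 + t(D_living) %*% TL
tl_power_oracle <- function(web, iters = 400) {
  n <- nrow(web$groups)
  D <- diet_matrix(web)
  M <- t(D[seq_len(n), , drop = FALSE])
  b <- 1 + D["import", ]
  cons <- web$groups$role == "consumer"
  M[!cons, ] <- 0
  b[!cons] <- 1
  tl <- b
  for (k in seq_len(iters)) tl <- b + as.numeric(M %*% tl)
  unname(tl)
}

# internal seed-scoping helper, used heavily by the property tests
with_local_seed <- enashift:::with_local_seed
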