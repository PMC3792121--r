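#' Compartment flow network
#'
#' The container consumed by the ENA indicator functions: an
#' `(n + 3) x (n + 3)` non-negative matrix of annual flows between the `n`
#' compartments plus three boundary nodes — `import` (row only), `export`
#' and `respiration` (columns only; respiration is the dissipative
#' boundary). `T[i, j]` is the flow from `i` to `j` in t/km2/yr.
#'
#' @param T Flow matrix, `(n + 3) x (n + 3)`, boundary rows/columns last in
#'   the order import, export, respiration.
#' @param labels Compartment labels (length `n + 3`).
#' @param role Character vector (length `n`): `"producer"`, `"consumer"`
#'   or `"detritus"` per compartment.
#' @param biomass,production,catch Optional per-compartment metadata
#'   (t/km2, t/km2/yr, t/km2/yr) used by the ecosystem-ratio and fisheries
#'   indicators.
#' @param balance_tol Relative steady-state tolerance: a warning is issued
#'   when any living compartment's |inflow − outflow| exceeds
#'   `balance_tol * TST`.
#' @param quiet Suppress the balance warning.
#' @return An object of class `flow_network`.
#' @export
flow_network <- function(T, labels, role, biomass = NULL, production = NULL,
                         catch = NULL, balance_tol = 1e-6, quiet = FALSE) {
  n <- length(role)
  stopifnot(nrow(T) == n + 3, ncol(T) == n + 3, length(labels) == n + 3)
  if (any(T < 0)) stop("flows must be non-negative", call. = FALSE)
  i_imp <- n + 1L; i_exp <- n + 2L; i_res <- n + 3L
  if (any(T[c(i_exp, i_res), ] != 0)) {
    stop("no flow may leave the export or respiration node", call. = FALSE)
  }
  if (any(T[, i_imp] != 0)) {
    stop("no flow may enter the import node", call. = FALSE)
  }
  net <- structure(
    list(
      T = T, labels = labels, role = role, n = n,
      biomass = biomass, production = production, catch = catch,
      idx = c(import = i_imp, export = i_exp, respiration = i_res)
    ),
    class = "flow_network"
  )
  tst <- total_system_throughput(net)
  if (!quiet && tst > 0) {
    imb <- compartment_imbalance(net)
    if (max(abs(imb)) > balance_tol * tst) {
      warning(
        "flow network out of steady-state balance; worst compartment: ",
        labels[which.max(abs(imb))],
        " (|in - out| = ", signif(max(abs(imb)), 3), ")",
        call. = FALSE
      )
    }
  }
  net
}

#' @export
print.flow_network <- function(x, ...) {
  cat(
    "<flow_network> ", x$n, " compartments + 3 boundary nodes, TST = ",
    signif(total_system_throughput(x), 6), " t/km2/yr\n",
    sep = ""
  )
  invisible(x)
}

# inflow - outflow per compartment (length n)
compartment_imbalance <- function(net) {
  n <- net$n
  colSums(net$T)[seq_len(n)] - rowSums(net$T)[seq_len(n)]
}

#' Flows of a network as a tibble
#'
#' @param x A [flow_network()].
#' @param ... Unused.
#' @return Long tibble `from`, `to`, `flow` with only non-zero flows.
#' @exportS3Method generics::tidy
tidy.flow_network <- function(x, ...) {
  idx <- which(x$T > 0, arr.ind = TRUE)
  tibble::tibble(
    from = x$labels[idx[, 1]],
    to = x$labels[idx[, 2]],
    flow = x$T[idx]
  )
}

#' Trophic levels from realized flows
#'
#' Flow-based analogue of [trophic_levels()]: consumer trophic level is 1
#' plus the inflow-weighted mean trophic level of its food sources, with
#' producers, detritus and imports fixed at 1.
#'
#' @param net A [flow_network()].
#' @return Tibble `group`, `TL`.
#' @export
trophic_levels_flow <- function(net) {
  n <- net$n
  T <- net$T
  inflow <- colSums(T[seq_len(n + 1), seq_len(n), drop = FALSE])
  M <- matrix(0, n, n)
  b <- rep(1, n)
  cons <- which(net$role == "consumer")
  for (j in cons) {
    if (inflow[j] > 0) {
      M[j, ] <- T[seq_len(n), j] / inflow[j]
      b[j] <- 1 + T[n + 1, j] / inflow[j] # imported food has TL 1
    }
  }
  tl <- solve(diag(n) - M, b)
  tibble::tibble(group = net$labels[seq_len(n)], TL = as.numeric(tl))
}
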