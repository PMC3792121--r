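#' Total system throughput
#'
#' Sum of every flow in the network, including imports, exports and
#' respiration (t/km2/yr).
#'
#' @param net A [flow_network()].
#' @export
total_system_throughput <- function(net) sum(net$T)

#' Information-theoretic flow decomposition
#'
#' Computes the Ulanowicz information indices of a flow network: average
#' mutual information (AMI), flow diversity (H, the Shannon upper bound of
#' AMI), ascendancy `A = TST * AMI`, development capacity `C = TST * H`,
#' relative ascendancy `A/C`, and redundancy `R` — the overhead carried by
#' the internal (compartment-to-compartment) flows, reported both in
#' flow-bits and as a percentage of capacity. Logarithms are base 2, so AMI
#' and H are in bits and A, C, R in t/km2/yr * bits.
#'
#' The identity `C = A + total overhead` holds exactly, and `R` never
#' exceeds the total overhead.
#'
#' @param net A [flow_network()].
#' @return A one-row tibble with columns `AMI`, `H`, `A`, `C`, `AC_ratio`,
#'   `R`, `R_pct_C`.
#' @export
information_decomposition <- function(net) {
  T <- net$T
  tst <- sum(T)
  if (tst <= 0) stop("information decomposition needs TST > 0", call. = FALSE)
  Ti <- rowSums(T)
  Tj <- colSums(T)
  pos <- which(T > 0, arr.ind = TRUE)
  f <- T[pos]
  ri <- Ti[pos[, 1]]
  cj <- Tj[pos[, 2]]
  ami <- sum(f / tst * log2(f * tst / (ri * cj)))
  h <- -sum(f / tst * log2(f / tst))
  n <- net$n
  internal <- pos[, 1] <= n & pos[, 2] <= n
  r <- -sum(f[internal] * log2(f[internal]^2 / (ri[internal] * cj[internal])))
  A <- tst * ami
  C <- tst * h
  tibble::tibble(
    AMI = ami, H = h, A = A, C = C,
    AC_ratio = if (C > 0) A / C else NA_real_,
    R = r, R_pct_C = if (C > 0) 100 * r / C else NA_real_
  )
}

#' Finn and predatory cycling indices
#'
#' Fraction of total system throughput that is recycled, computed from the
#' structure (Leontief) matrix `N = (I - G)^-1`, where `G_ij = T_ij / T_j`
#' is the fraction of compartment `j`'s throughflow received from `i`
#' (input convention). The cycled portion of compartment `i`'s throughflow
#' is `(N_ii - 1) / N_ii * T_i`. With `include_detritus = FALSE` the
#' detritus compartments and all their flows are removed before the
#' computation, yielding the predatory cycling index (recycling without
#' detritus).
#'
#' @param net A [flow_network()].
#' @param include_detritus Keep detritus compartments (Finn cycling index,
#'   the default) or drop them (predatory cycling index).
#' @return A single dimensionless fraction in \[0, 1\].
#' @export
finn_cycle_index <- function(net, include_detritus = TRUE) {
  n <- net$n
  keep <- seq_len(n)
  if (!include_detritus) keep <- keep[net$role != "detritus"]
  idx <- c(keep, n + 1L, n + 2L, n + 3L)
  T <- net$T[idx, idx, drop = FALSE]
  m <- length(keep)
  tst <- sum(T)
  if (tst == 0 || m == 0) return(0)
  inflow <- colSums(T[seq_len(m + 1), seq_len(m), drop = FALSE])
  G <- T[seq_len(m), seq_len(m), drop = FALSE]
  posin <- inflow > 0
  G[, posin] <- sweep(G[, posin, drop = FALSE], 2, inflow[posin], `/`)
  G[, !posin] <- 0
  N <- tryCatch(
    solve(diag(m) - G),
    error = function(e) {
      stop("structure matrix is singular; offending compartment near: ",
        net$labels[keep[which.max(colSums(G))]],
        call. = FALSE
      )
    }
  )
  dn <- diag(N)
  cycled <- ifelse(dn > 0, (dn - 1) / dn * inflow, 0)
  sum(cycled) / tst
}

#' Mean path length
#'
#' Average number of compartments a unit of inflow traverses before it
#' leaves the system: `TST / total boundary input` (Finn's convention,
#' where boundary input includes primary production entering the producers
#' and all other imports). `denominator = "output"` divides by
#' exports + respiration instead; the two agree at steady state.
#'
#' @param net A [flow_network()].
#' @param denominator `"input"` (default) or `"output"`.
#' @return Dimensionless path length >= 1.
#' @export
mean_path_length <- function(net, denominator = c("input", "output")) {
  denominator <- match.arg(denominator)
  n <- net$n
  den <- if (denominator == "input") {
    sum(net$T[n + 1L, ])
  } else {
    sum(net$T[, c(n + 2L, n + 3L)])
  }
  if (den <= 0) stop("mean path length undefined: zero boundary ", denominator,
    call. = FALSE
  )
  total_system_throughput(net) / den
}

#' Proportional flow to detritus
#'
#' Sum of all flows entering detritus compartments as a fraction of total
#' system throughput.
#'
#' @param net A [flow_network()].
#' @export
flow_to_detritus_fraction <- function(net) {
  n <- net$n
  det <- which(net$role == "detritus")
  if (length(det) == 0) return(0)
  sum(net$T[, det]) / total_system_throughput(net)
}

#' Ecosystem production, respiration and catch totals
#'
#' @param net A [flow_network()] carrying `biomass`, `production` and
#'   `catch` metadata (as produced by [to_flow_network()] or
#'   [annual_flow_snapshots()]).
#' @return One-row tibble: `TPP_TR` (total primary production / total
#'   respiration), `ToTP_ToTB` (total production / total living biomass,
#'   1/yr) and `TotC` (total catch, t/km2/yr).
#' @export
ecosystem_ratios <- function(net) {
  if (is.null(net$biomass) || is.null(net$production)) {
    stop("network carries no biomass/production metadata", call. = FALSE)
  }
  n <- net$n
  living <- net$role != "detritus"
  tpp <- sum(net$production[net$role == "producer"])
  tr <- sum(net$T[, n + 3L])
  totp <- sum(net$production[living])
  totb <- sum(net$biomass[living])
  if (tr <= 0) stop("total respiration is zero; TPP/TR undefined", call. = FALSE)
  if (totb <= 0) stop("total living biomass is zero", call. = FALSE)
  totc <- sum(if (is.null(net$catch)) 0 else net$catch)
  tibble::tibble(TPP_TR = tpp / tr, ToTP_ToTB = totp / totb, TotC = totc)
}

#' Fisheries impact indices
#'
#' `mTLc` is the catch-weighted mean trophic level of the landings. `PPR_PP`
#' is the primary production required to sustain the catch, found by tracing
#' each caught flow back through the inflow-proportioned flow graph until it
#' reaches primary producers, detritus or imports (cycles are resolved by a
#' linear solve), divided by total primary production.
#'
#' @param net A [flow_network()] with `catch` and `production` metadata.
#' @param tl Optional tibble from [trophic_levels_flow()] /
#'   [trophic_levels()]; computed from the network flows when omitted.
#' @return One-row tibble `mTLc`, `PPR_PP`. `mTLc` is `NA` when total catch
#'   is zero.
#' @export
fisheries_indices <- function(net, tl = NULL) {
  if (is.null(net$catch)) stop("network carries no catch metadata", call. = FALSE)
  if (is.null(tl)) tl <- trophic_levels_flow(net)
  n <- net$n
  y <- net$catch
  tot <- sum(y)
  mtlc <- if (tot > 0) sum(y * tl$TL) / tot else NA_real_

  # primary production required per unit production of each compartment
  T <- net$T
  inflow <- colSums(T[seq_len(n + 1), seq_len(n), drop = FALSE])
  prod <- net$production
  cons <- which(net$role == "consumer" & inflow > 0 & prod > 0)
  p <- rep(1, n) # producers and detritus anchor the recursion at 1
  if (length(cons) > 0) {
    W <- matrix(0, length(cons), length(cons))
    b <- numeric(length(cons))
    for (k in seq_along(cons)) {
      j <- cons[k]
      g_j <- prod[j] / inflow[j]
      frac <- T[seq_len(n + 1), j] / inflow[j]
      src_cons <- match(seq_len(n), cons)
      for (i in seq_len(n)) {
        if (frac[i] > 0) {
          if (!is.na(src_cons[i]) && i %in% cons) {
            W[k, src_cons[i]] <- frac[i] / g_j
          } else {
            b[k] <- b[k] + frac[i] / g_j
          }
        }
      }
      b[k] <- b[k] + frac[n + 1] / g_j # imported food counts as primary source
    }
    p[cons] <- solve(diag(length(cons)) - W, b)
  }
  p[net$role == "consumer" & !(seq_len(n) %in% cons)] <- 0
  tpp <- sum(prod[net$role == "producer"])
  ppr <- sum(y * p)
  tibble::tibble(
    mTLc = mtlc,
    PPR_PP = if (tpp > 0) ppr / tpp else NA_real_
  )
}

#' Kempton Q biomass diversity index
#'
#' Inter-quartile slope of the descending biomass-dominance curve over the
#' upper-trophic-level groups (the Ecopath adaptation of the Kempton-Taylor
#' index): `Q = (S / 2) / log10(B25 / B75)` where `S` is the number of
#' groups with trophic level at or above `tl_min` and `B25`, `B75` are the
#' biomasses at the lower and upper inter-quartile positions of the sorted
#' curve. Larger values mean a more even biomass distribution.
#'
#' @param biomass Per-group biomass vector (t/km2).
#' @param tl Per-group trophic level vector (same order).
#' @param tl_min Trophic level threshold for inclusion (default 3).
#' @return Dimensionless index, or `NA` when fewer than 2 groups qualify or
#'   the quartile biomasses coincide.
#' @export
kempton_q <- function(biomass, tl, tl_min = 3) {
  stopifnot(length(biomass) == length(tl))
  keep <- !is.na(tl) & tl >= tl_min & !is.na(biomass) & biomass > 0
  b <- sort(biomass[keep], decreasing = TRUE)
  s <- length(b)
  if (s < 2) return(NA_real_)
  i25 <- max(1L, ceiling(0.25 * s))
  i75 <- min(s, ceiling(0.75 * s))
  if (b[i25] <= b[i75] || i25 == i75) return(NA_real_)
  (s / 2) / log10(b[i25] / b[i75])
}

#' All fifteen ecosystem indicators of a flow network
#'
#' Assembles the full indicator set for one annual network: total system
#' throughput; the information indices (A, C, A/C, AMI, H, redundancy in
#' flow-bits and as % of capacity); Finn and predatory cycling; mean path
#' length; proportional flow to detritus; TPP/TR; total production over
#' total biomass; total catch; PPR/PP; mean trophic level of the catch; and
#' Kempton Q. Individual failures propagate as `NA` fields rather than
#' aborting the set.
#'
#' @param net A [flow_network()] with metadata.
#' @param year Optional calendar year recorded in the output.
#' @param kempton_tl_min Trophic-level threshold for Kempton Q.
#' @return A one-row tibble.
#' @export
ena_indicators <- function(net, year = NA_integer_, kempton_tl_min = 3) {
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  info <- tryCatch(information_decomposition(net), error = function(e) {
    tibble::tibble(
      AMI = NA_real_, H = NA_real_, A = NA_real_, C = NA_real_,
      AC_ratio = NA_real_, R = NA_real_, R_pct_C = NA_real_
    )
  })
  ratios <- tryCatch(ecosystem_ratios(net), error = function(e) {
    tibble::tibble(TPP_TR = NA_real_, ToTP_ToTB = NA_real_, TotC = NA_real_)
  })
  tl <- tryCatch(trophic_levels_flow(net), error = function(e) NULL)
  fish <- tryCatch(fisheries_indices(net, tl), error = function(e) {
    tibble::tibble(mTLc = NA_real_, PPR_PP = NA_real_)
  })
  q <- if (is.null(tl) || is.null(net$biomass)) NA_real_ else {
    safe(kempton_q(net$biomass, tl$TL, tl_min = kempton_tl_min))
  }
  tibble::tibble(
    year = year,
    TST = total_system_throughput(net),
    A = info$A, C = info$C, AC_ratio = info$AC_ratio,
    AMI = info$AMI, H = info$H, R = info$R, R_pct_C = info$R_pct_C,
    FCI = safe(finn_cycle_index(net, include_detritus = TRUE)),
    PCI = safe(finn_cycle_index(net, include_detritus = FALSE)),
    MPL = safe(mean_path_length(net)),
    PFD = safe(flow_to_detritus_fraction(net)),
    TPP_TR = ratios$TPP_TR, ToTP_ToTB = ratios$ToTP_ToTB, TotC = ratios$TotC,
    PPR_PP = fish$PPR_PP, mTLc = fish$mTLc,
    KemptonQ = q
  )
}

#' Indicator time series over annual flow networks
#'
#' @param nets List of [flow_network()]s, one per year (e.g. from
#'   [annual_flow_snapshots()]).
#' @param years Calendar years (defaults to names of `nets` or `1:length`).
#' @param kempton_tl_min Passed to [ena_indicators()].
#' @return A tibble with one row per year, 18 columns (year + 15 indicators
#'   + redundancy in both units and capacity components).
#' @export
indicator_series <- function(nets, years = NULL, kempton_tl_min = 3) {
  if (is.null(years)) {
    years <- if (!is.null(names(nets))) as.integer(names(nets)) else seq_along(nets)
  }
  stopifnot(length(years) == length(nets))
  purrr::map2_dfr(
    nets, years,
    ~ ena_indicators(.x, year = .y, kempton_tl_min = kempton_tl_min)
  )
}
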