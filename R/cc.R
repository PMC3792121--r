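#' Chronological clustering of a multivariate time series
#'
#' Groups sequential years into homogeneous segments. Series are first
#' z-score normalized and Euclidean distances between years computed.
#' Agglomeration is restricted to temporally adjacent clusters and uses
#' proportional-link linkage: the distance between two clusters is the
#' `connectedness`-quantile of their between-cluster pairwise distances.
#' Each candidate fusion is subjected to a permutation test of homogeneity
#' (object memberships permuted between the two clusters, linkage distance
#' recomputed): the fusion is accepted unless the observed linkage is
#' significantly large at level `alpha` (the clustering-intensity
#' parameter). Rejected fusions become segment boundaries. After the main
#' pass each remaining boundary is re-tested against the final adjacent
#' segments and removed if the test no longer rejects, which guards
#' against spurious boundaries from early small-cluster comparisons.
#'
#' When the number of distinct label arrangements is small the test is
#' evaluated by exhaustive enumeration (and fusions whose minimum
#' attainable p-value exceeds `alpha` are accepted outright); otherwise
#' `n_perm` random permutations are used. All randomness is governed by
#' `seed`.
#'
#' @param data Data frame with a `year` column and numeric series columns;
#'   at least 4 years, no missing values.
#' @param alpha Clustering-intensity significance level (default 0.01).
#' @param connectedness Fraction of between-cluster links used by the
#'   proportional-link linkage (default 0.5).
#' @param n_perm Number of random permutations when enumeration is
#'   infeasible (default 999).
#' @param seed Integer seed making the permutation test deterministic.
#' @return An object of class `cc_partition`: `segments` (tibble `start`,
#'   `end`, `n`), `boundaries` (first year of each new segment) and the
#'   configuration.
#' @export
chronological_clustering <- function(data, alpha = 0.01, connectedness = 0.5,
                                     n_perm = 999, seed = 1) {
  stopifnot("year" %in% names(data))
  years <- data$year
  vars <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], "year")
  X <- as.matrix(data[vars])
  n <- nrow(X)
  if (n < 4) stop("chronological clustering needs at least 4 years", call. = FALSE)
  if (anyNA(X)) stop("missing values in input", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("all variables are constant", call. = FALSE)
  Xz <- scale(X[, keep, drop = FALSE])
  D <- as.matrix(stats::dist(Xz))

  co <- connectedness
  linkage <- function(a_idx, b_idx) {
    d <- as.vector(D[a_idx, b_idx, drop = FALSE])
    sort(d)[max(1L, ceiling(co * length(d)))]
  }

  with_local_seed(seed, cc_run(
    D, years, n, alpha, co, n_perm, linkage, seed
  ))
}

# the clustering proper; runs inside a seed scope so every permutation is
# deterministic given the configuration seed
cc_run <- function(D, years, n, alpha, co, n_perm, linkage, seed) {
  # permutation test of homogeneity for the fusion of two adjacent clusters;
  # returns TRUE when the fusion is accepted (H0 of homogeneity retained)
  accept_fusion <- function(a_idx, b_idx) {
    na <- length(a_idx)
    nb <- length(b_idx)
    pool <- c(a_idx, b_idx)
    m <- na + nb
    n_arr <- choose(m, na)
    if (n_arr <= 1 / alpha) return(TRUE) # test cannot reject at this level
    obs <- linkage(a_idx, b_idx)
    if (n_arr <= 2000) {
      combos <- utils::combn(m, na)
      stats_perm <- apply(combos, 2, function(sel) {
        linkage(pool[sel], pool[-sel])
      })
      p <- mean(stats_perm >= obs - 1e-12)
    } else {
      cnt <- 0L
      for (r in seq_len(n_perm)) {
        sel <- sample.int(m, na)
        if (linkage(pool[sel], pool[-sel]) >= obs - 1e-12) cnt <- cnt + 1L
      }
      p <- (1 + cnt) / (1 + n_perm)
    }
    p > alpha
  }

  clusters <- as.list(seq_len(n))
  sealed <- logical(n - 1) # boundary after cluster k confirmed
  repeat {
    k <- length(clusters)
    if (k == 1) break
    cand <- which(!sealed[seq_len(k - 1)])
    if (length(cand) == 0) break
    lk <- vapply(cand, function(j) linkage(clusters[[j]], clusters[[j + 1]]),
      numeric(1)
    )
    j <- cand[which.min(lk)]
    if (accept_fusion(clusters[[j]], clusters[[j + 1]])) {
      clusters[[j]] <- c(clusters[[j]], clusters[[j + 1]])
      clusters[[j + 1]] <- NULL
      sealed <- sealed[-j]
    } else {
      sealed[j] <- TRUE
    }
  }

  # posterior pass: re-test each surviving boundary against the final
  # adjacent segments with a selection-adjusted null. A boundary that
  # survived agglomeration is the pooled segment's worst junction, so the
  # observed linkage is compared with the permutation distribution of the
  # maximum linkage over the contiguous splits whose smaller side is at
  # least the observed smaller side (at the even split this degenerates to
  # the plain fixed-split test, preserving power at clean junctions)
  accept_boundary <- function(a_idx, b_idx) {
    pool <- c(a_idx, b_idx)
    m <- length(pool)
    ms <- min(length(a_idx), length(b_idx))
    if (m < 4) return(accept_fusion(a_idx, b_idx))
    obs <- linkage(a_idx, b_idx)
    ks <- ms:(m - ms)
    np <- min(n_perm, 999L)
    cnt <- 0L
    for (r in seq_len(np)) {
      perm <- pool[sample.int(m, m)]
      mx <- 0
      for (k in ks) {
        lk <- linkage(perm[1:k], perm[(k + 1):m])
        if (lk > mx) mx <- lk
      }
      if (mx >= obs - 1e-12) {
        cnt <- cnt + 1L
        if ((1 + cnt) / (1 + np) > alpha) return(TRUE) # early accept
      }
    }
    (1 + cnt) / (1 + np) > alpha
  }
  repeat {
    k <- length(clusters)
    if (k == 1) break
    removed <- FALSE
    for (j in seq_len(k - 1)) {
      if (accept_boundary(clusters[[j]], clusters[[j + 1]])) {
        clusters[[j]] <- c(clusters[[j]], clusters[[j + 1]])
        clusters[[j + 1]] <- NULL
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }

  starts <- vapply(clusters, function(ix) min(ix), integer(1))
  ends <- vapply(clusters, function(ix) max(ix), integer(1))
  segments <- tibble::tibble(
    start = years[starts], end = years[ends], n = ends - starts + 1L
  )
  structure(
    list(
      segments = segments,
      boundaries = years[starts[-1]],
      config = list(
        alpha = alpha, connectedness = co, n_perm = n_perm, seed = seed
      )
    ),
    class = "cc_partition"
  )
}

#' @export
print.cc_partition <- function(x, ...) {
  cat("<cc_partition> ", nrow(x$segments), " segment(s)",
    if (length(x$boundaries) > 0) {
      paste0("; boundaries at ", paste(x$boundaries, collapse = ", "))
    } else {
      "; no boundaries"
    }, "\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cc_partition <- function(x, ...) x$segments
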