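#' Standardized principal component index of a multivariate time series
#'
#' PCA on the correlation matrix of (optionally log-transformed) annual
#' series. PC1 scores of forcing variables serve as a pressure index; PC1
#' of modelled biomass as an index of biological state. The log transform
#' is `ln(1 + x)`, applied sign-preservingly (`sign(x) * ln(1 + |x|)`) so
#' anomaly series with negative values remain transformable. Each
#' component is oriented so that its largest-magnitude loading is
#' positive, making scores reproducible across runs.
#'
#' @param data Data frame with a `year` column and at least two numeric
#'   series columns; at least 3 years; no missing values.
#' @param transform Apply the signed `ln(1 + x)` transform (default TRUE).
#' @return An object of class `pca_result` with `loadings` (tibble
#'   `series` x component), `scores` (tibble `year` x component, zero
#'   mean), and `variance_explained` (percent per component,
#'   non-increasing).
#' @export
pca_index <- function(data, transform = TRUE) {
  stopifnot("year" %in% names(data))
  vars <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], "year")
  if (length(vars) < 2) stop("need at least 2 variables", call. = FALSE)
  X <- as.matrix(data[vars])
  if (nrow(X) < 3) stop("need at least 3 years", call. = FALSE)
  if (anyNA(X)) stop("missing values in PCA input", call. = FALSE)
  if (transform) X <- sign(X) * log1p(abs(X))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop(
      "zero-variance variable(s): ", paste(vars[sds == 0], collapse = ", "),
      call. = FALSE
    )
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  # deterministic sign: largest-|loading| variable of each PC is positive
  for (k in seq_len(ncol(pc$rotation))) {
    imax <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[imax, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  loadings <- tibble::as_tibble(pc$rotation)
  loadings <- dplyr::bind_cols(tibble::tibble(series = vars), loadings)
  scores <- tibble::as_tibble(pc$x)
  scores <- dplyr::bind_cols(tibble::tibble(year = data$year), scores)
  structure(
    list(
      loadings = loadings, scores = scores, variance_explained = ve,
      transform = transform
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", nrow(x$loadings), " variables, ",
    nrow(x$scores), " years; PC1 explains ",
    round(x$variance_explained[1], 1), "% of variance\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pca_result <- function(x, ...) {
  tidyr::pivot_longer(x$loadings, -"series",
    names_to = "component", values_to = "loading"
  )
}

#' @exportS3Method generics::glance
glance.pca_result <- function(x, ...) {
  tibble::tibble(
    component = paste0("PC", seq_along(x$variance_explained)),
    variance_explained = x$variance_explained
  )
}

#' STARS on principal component scores
#'
#' Composition of [pca_index()] and [stars()]: detects step changes in a
#' PC-score index series (pressure or state index).
#'
#' @param pca A `pca_result`.
#' @param component Component number (default 1).
#' @param ... Passed to [stars()] (`alpha`, `cutoff`, `huber`).
#' @return A `stars_result`.
#' @export
stars_on_scores <- function(pca, component = 1, ...) {
  col <- paste0("PC", component)
  if (!col %in% names(pca$scores)) {
    stop("no component ", component, " in the PCA result", call. = FALSE)
  }
  stars(pca$scores[[col]], years = pca$scores$year, ...)
}
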