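#' Traffic-light table of annual series
#'
#' Categorizes each series into quintiles over its own time span (1 =
#' lowest 0-20%, 5 = highest 80-100%), with ties assigned to the lower
#' bin, and orders the rows by a per-variable score (typically the PC1
#' loadings, descending). Constant series are put in the middle bin with a
#' warning.
#'
#' @param data Data frame with a `year` column and numeric series columns.
#' @param ordering Optional ordering score: a named numeric vector
#'   (series -> score) or a `pca_result` (PC1 loadings are used). Defaults
#'   to the column order.
#' @return An object of class `traffic_light`: tibble `series`, `year`,
#'   `value`, `bin` with `series` an ordered factor, plus the palette.
#' @export
traffic_light <- function(data, ordering = NULL) {
  stopifnot("year" %in% names(data))
  vars <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], "year")
  if (anyNA(data[vars])) stop("missing values in input", call. = FALSE)
  n <- nrow(data)
  bins <- purrr::map(vars, function(v) {
    x <- data[[v]]
    if (max(x) == min(x)) {
      warning("constant series '", v, "' assigned to the middle bin",
        call. = FALSE
      )
      return(rep(3L, n))
    }
    r <- rank(x, ties.method = "min")
    as.integer(ceiling(5 * r / n))
  })
  names(bins) <- vars

  score <- if (is.null(ordering)) {
    stats::setNames(rev(seq_along(vars)), vars)
  } else if (inherits(ordering, "pca_result")) {
    stats::setNames(ordering$loadings$PC1, ordering$loadings$series)
  } else {
    ordering
  }
  ord <- vars[order(-score[vars])]

  cells <- purrr::map_dfr(vars, function(v) {
    tibble::tibble(
      series = v, year = data$year, value = data[[v]], bin = bins[[v]]
    )
  })
  cells$series <- factor(cells$series, levels = ord)
  structure(
    list(
      cells = cells,
      palette = c(
        `1` = "#1a9850", `2` = "#91cf60", `3` = "#ffffbf",
        `4` = "#fc8d59", `5` = "#d73027"
      )
    ),
    class = "traffic_light"
  )
}

#' @export
print.traffic_light <- function(x, ...) {
  cat("<traffic_light> ", nlevels(x$cells$series), " series x ",
    length(unique(x$cells$year)), " years\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.traffic_light <- function(x, ...) x$cells

#' Traffic-light table in wide form
#'
#' @param x A `traffic_light`.
#' @return Tibble with one row per series (in display order) and one
#'   column per year holding the quintile bin.
#' @export
traffic_light_table <- function(x) {
  out <- tidyr::pivot_wider(
    x$cells[c("series", "year", "bin")],
    names_from = "year", values_from = "bin"
  )
  dplyr::arrange(out, .data$series)
}
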