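#' Plot a STARS result
#'
#' Time series with the weighted regime means as step segments and
#' detected shift years as vertical lines (dashed when end-truncated).
#'
#' @param object A `stars_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.stars_result <- function(object, ...) {
  regimes <- object$regimes
  p <- ggplot2::ggplot(
    object$data, ggplot2::aes(x = .data$year, y = .data$value)
  ) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_segment(
      data = regimes,
      ggplot2::aes(
        x = .data$start, xend = .data$end,
        y = .data$weighted_mean, yend = .data$weighted_mean
      ),
      colour = "red", linewidth = 0.9
    ) +
    ggplot2::labs(x = "year", y = "value") +
    ggplot2::theme_minimal()
  if (nrow(object$shifts) > 0) {
    p <- p + ggplot2::geom_vline(
      data = object$shifts,
      ggplot2::aes(xintercept = .data$year, linetype = .data$end_truncated),
      colour = "red", alpha = 0.5, show.legend = FALSE
    ) +
      ggplot2::scale_linetype_manual(
        values = c(`FALSE` = "solid", `TRUE` = "dashed")
      )
  }
  p
}

#' Plot a traffic-light table
#'
#' Quintile-coloured tile plot, rows ordered by the supplied scores
#' (green = lowest quintile, red = highest).
#'
#' @param object A `traffic_light`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.traffic_light <- function(object, ...) {
  ggplot2::ggplot(
    object$cells,
    ggplot2::aes(x = .data$year, y = .data$series, fill = factor(.data$bin))
  ) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.2) +
    ggplot2::scale_fill_manual(
      values = object$palette, name = "quintile",
      labels = c("0-20%", "20-40%", "40-60%", "60-80%", "80-100%")
    ) +
    ggplot2::scale_y_discrete(limits = rev(levels(object$cells$series))) +
    ggplot2::labs(x = "year", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot simulated biomass trajectories
#'
#' @param object A `trajectory` from [simulate_foodweb()].
#' @param groups Optional subset of group names.
#' @param ... Unused.
#' @return A ggplot object, one facet per group (free y scale).
#' @exportS3Method ggplot2::autoplot
autoplot.trajectory <- function(object, groups = NULL, ...) {
  d <- tidy.trajectory(object)
  if (!is.null(groups)) d <- d[d$group %in% groups, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$year, y = .data$biomass)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~group, scales = "free_y") +
    ggplot2::labs(x = "year", y = "biomass (t/km2)") +
    ggplot2::theme_minimal()
}

#' Plot PCA loadings and score trajectory
#'
#' @param object A `pca_result`.
#' @param what `"scores"` (PC1/PC2 trajectory with years connected
#'   chronologically) or `"loadings"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pca_result <- function(object, what = c("scores", "loadings"), ...) {
  what <- match.arg(what)
  if (what == "scores") {
    ggplot2::ggplot(
      object$scores, ggplot2::aes(x = .data$PC1, y = .data$PC2)
    ) +
      ggplot2::geom_path(colour = "grey60") +
      ggplot2::geom_text(ggplot2::aes(label = .data$year), size = 2.7) +
      ggplot2::labs(
        x = sprintf("PC1 (%.0f%%)", object$variance_explained[1]),
        y = sprintf("PC2 (%.0f%%)", object$variance_explained[2])
      ) +
      ggplot2::theme_minimal()
  } else {
    d <- tidy.pca_result(object)
    d <- d[d$component %in% c("PC1", "PC2"), ]
    d <- tidyr::pivot_wider(d, names_from = "component", values_from = "loading")
    ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
      ggplot2::geom_segment(
        ggplot2::aes(xend = 0, yend = 0), colour = "grey70"
      ) +
      ggplot2::geom_text(ggplot2::aes(label = .data$series), size = 2.7) +
      ggplot2::labs(x = "PC1 loading", y = "PC2 loading") +
      ggplot2::theme_minimal()
  }
}

#' Plot indicator anomaly series
#'
#' Anomalies of each indicator relative to its first year, one facet per
#' indicator.
#'
#' @param series Indicator tibble from [indicator_series()].
#' @param indicators Optional subset of indicator column names.
#' @return A ggplot object.
#' @export
plot_indicator_anomalies <- function(series, indicators = NULL) {
  keep <- setdiff(names(series), c("A", "C", "R"))
  d <- anomaly_series(series[keep])
  if (!is.null(indicators)) d <- d[c("year", indicators)]
  long <- tidyr::pivot_longer(d, -"year",
    names_to = "indicator", values_to = "anomaly"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$anomaly)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~indicator, scales = "free_y") +
    ggplot2::labs(x = "year", y = "anomaly (vs first year)") +
    ggplot2::theme_minimal()
}
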