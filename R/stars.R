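#' Sequential t-test analysis of regime shifts (STARS)
#'
#' Rodionov's sequential algorithm for detecting step changes in the mean
#' of a time series. The detection threshold is
#' `diff = t_crit(alpha, 2l - 2) * sqrt(2 * sigma_l^2 / l)`, with
#' `sigma_l^2` the average variance over all consecutive windows of length
#' `l`. A value outside the current regime mean +/- `diff` opens a
#' candidate regime; the candidate is confirmed only if the cumulative
#' Huber-weighted regime shift index (RSI) over the following `l` years
#' stays positive. Outliers beyond `huber` standard deviations are
#' down-weighted (weight `huber / |z|`) both in the RSI and in the regime
#' means. Shifts that can only be confirmed within the final `l` years are
#' reported but flagged `end_truncated` (they are conventionally discarded
#' from interpretation).
#'
#' @param x Numeric series (annual values, no missing values), or a single
#'   -column data frame.
#' @param years Optional calendar years (defaults to `1:length(x)`).
#' @param alpha Significance level of the t-test (default 0.05).
#' @param cutoff Cut-off regime length `l` in years (default 5; use 10 for
#'   slow biomass series).
#' @param huber Huber weight parameter (default 3).
#' @return An object of class `stars_result` with elements `shifts`
#'   (tibble `year`, `index`, `rsi`, `direction`, `end_truncated`),
#'   `regimes` (tibble `start`, `end`, `mean`, `weighted_mean`), the
#'   per-candidate `rsi` trace and the configuration.
#' @export
stars <- function(x, years = NULL, alpha = 0.05, cutoff = 5, huber = 3) {
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    if ("year" %in% names(x) && is.null(years)) years <- x$year
    val <- setdiff(names(x)[num], "year")
    if (length(val) != 1) {
      stop("stars() needs a single series; use detect_shifts() for tables",
        call. = FALSE
      )
    }
    x <- x[[val]]
  }
  x <- as.numeric(x)
  n <- length(x)
  if (anyNA(x)) stop("series contains missing values", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  if (cutoff < 2) stop("cutoff must be >= 2", call. = FALSE)
  if (huber <= 0) stop("huber must be > 0", call. = FALSE)
  if (n < 2 * cutoff) {
    stop("series must have at least 2 * cutoff observations", call. = FALSE)
  }
  if (is.null(years)) years <- seq_len(n)
  l <- as.integer(cutoff)

  # average variance of consecutive l-windows
  nw <- n - l + 1L
  vars <- vapply(seq_len(nw), function(s) stats::var(x[s:(s + l - 1L)]),
    numeric(1)
  )
  sigma2 <- mean(vars)
  sigma <- sqrt(sigma2)
  tcrit <- stats::qt(1 - alpha / 2, df = 2 * l - 2)
  diff <- tcrit * sqrt(2 * sigma2 / l)

  hub_mean <- function(v) {
    if (sigma == 0) return(mean(v))
    m <- mean(v)
    for (it in 1:2) {
      z <- (v - m) / sigma
      w <- ifelse(abs(z) > huber, huber / abs(z), 1)
      m <- sum(w * v) / sum(w)
    }
    m
  }

  shift_idx <- integer()
  shift_rsi <- numeric()
  shift_dir <- character()
  shift_trunc <- logical()
  rsi_trace <- rep(0, n)

  regime_start <- 1L
  # initial regime mean from the first l points
  cur_mean <- hub_mean(x[seq_len(min(l, n))])
  i <- l + 1L
  while (i <= n) {
    lo <- cur_mean - diff
    hi <- cur_mean + diff
    if (x[i] > hi || x[i] < lo) {
      up <- x[i] > hi
      level <- if (up) hi else lo
      jmax <- min(i + l - 1L, n)
      csum <- 0
      ok <- TRUE
      for (j in i:jmax) {
        z <- (x[j] - level) / sigma
        w <- if (abs(z) > huber) huber / abs(z) else 1
        dev <- if (up) (x[j] - level) else (level - x[j])
        csum <- csum + w * dev / (l * sigma)
        if (csum < 0) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        rsi_trace[i] <- if (up) csum else -csum
        shift_idx <- c(shift_idx, i)
        shift_rsi <- c(shift_rsi, csum)
        shift_dir <- c(shift_dir, if (up) "up" else "down")
        shift_trunc <- c(shift_trunc, jmax - i + 1L < l)
        regime_start <- i
        cur_mean <- hub_mean(x[i:jmax])
        i <- i + 1L
        next
      }
    }
    # no shift: absorb x[i] into the current regime mean
    cur_mean <- hub_mean(x[regime_start:i])
    i <- i + 1L
  }

  bounds <- c(1L, shift_idx, n + 1L)
  regimes <- tibble::tibble(
    start = years[utils::head(bounds, -1)],
    end = years[utils::tail(bounds, -1) - 1L],
    mean = vapply(
      seq_len(length(bounds) - 1L),
      function(k) mean(x[bounds[k]:(bounds[k + 1L] - 1L)]), numeric(1)
    ),
    weighted_mean = vapply(
      seq_len(length(bounds) - 1L),
      function(k) hub_mean(x[bounds[k]:(bounds[k + 1L] - 1L)]), numeric(1)
    )
  )
  structure(
    list(
      shifts = tibble::tibble(
        year = years[shift_idx], index = shift_idx, rsi = shift_rsi,
        direction = shift_dir, end_truncated = shift_trunc
      ),
      regimes = regimes,
      rsi = tibble::tibble(year = years, rsi = rsi_trace),
      data = tibble::tibble(year = years, value = x),
      config = list(
        alpha = alpha, cutoff = l, huber = huber, diff = diff,
        sigma_l = sigma
      )
    ),
    class = "stars_result"
  )
}

#' @export
print.stars_result <- function(x, ...) {
  cat("<stars_result> alpha = ", x$config$alpha, ", l = ", x$config$cutoff,
    ", h = ", x$config$huber, "\n",
    sep = ""
  )
  if (nrow(x$shifts) == 0) {
    cat("no shifts detected\n")
  } else {
    print(x$shifts)
  }
  invisible(x)
}

#' @rdname stars
#' @param include_truncated Keep shifts only confirmable in the final
#'   `cutoff` years.
#' @export
shift_years <- function(x, include_truncated = FALSE) {
  s <- x$shifts
  if (!include_truncated) s <- s[!s$end_truncated, , drop = FALSE]
  s$year
}

#' @exportS3Method generics::tidy
tidy.stars_result <- function(x, ...) x$shifts

#' @exportS3Method generics::glance
glance.stars_result <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$data),
    n_shifts = nrow(x$shifts),
    n_regimes = nrow(x$regimes),
    sigma_l = x$config$sigma_l,
    diff = x$config$diff
  )
}

#' STARS over every series of a year-indexed table
#'
#' Applies [stars()] column-wise to a wide table of annual series.
#'
#' @param data Data frame with a `year` column and one numeric column per
#'   series.
#' @param alpha,cutoff,huber STARS parameters, see [stars()].
#' @return Tibble `series`, `year`, `rsi`, `direction`, `end_truncated`
#'   with one row per detected shift.
#' @export
detect_shifts <- function(data, alpha = 0.05, cutoff = 5, huber = 3) {
  stopifnot("year" %in% names(data))
  vars <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], "year")
  purrr::map_dfr(vars, function(v) {
    res <- stars(data[[v]],
      years = data$year, alpha = alpha, cutoff = cutoff, huber = huber
    )
    s <- res$shifts
    if (nrow(s) == 0) return(tibble::tibble())
    tibble::tibble(
      series = v, year = s$year, rsi = s$rsi, direction = s$direction,
      end_truncated = s$end_truncated
    )
  })
}

#' Regime-wise coefficient of variation
#'
#' Sample coefficient of variation (`sd / |mean|`, n - 1 denominator) of
#' each series over closed year periods.
#'
#' @param data Data frame with a `year` column and numeric series columns.
#' @param periods List of `c(start, end)` year pairs (closed intervals), or
#'   a two-column data frame.
#' @return Tibble `series`, `start`, `end`, `period`, `cv`; `cv` is `NA`
#'   when the period mean is zero.
#' @export
cv_by_period <- function(data, periods) {
  stopifnot("year" %in% names(data))
  if (is.data.frame(periods)) {
    periods <- purrr::map(seq_len(nrow(periods)), ~ unlist(periods[.x, 1:2]))
  }
  vars <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], "year")
  purrr::map_dfr(periods, function(p) {
    if (p[1] < min(data$year) || p[2] > max(data$year)) {
      stop("period ", p[1], "-", p[2], " outside the series span", call. = FALSE)
    }
    rows <- data$year >= p[1] & data$year <= p[2]
    purrr::map_dfr(vars, function(v) {
      x <- data[[v]][rows]
      m <- mean(x)
      tibble::tibble(
        series = v, start = p[1], end = p[2],
        period = paste0(p[1], "-", p[2]),
        cv = if (m == 0) NA_real_ else stats::sd(x) / abs(m)
      )
    })
  })
}

#' Anomaly series
#'
#' Deviation of each series from a reference: its initial value (default,
#' matching forcing-anomaly plots) or its period mean.
#'
#' @param data Data frame with a `year` column and numeric series columns.
#' @param reference `"initial"` or `"mean"`.
#' @return Tibble of the same shape with anomalies in place of values.
#' @export
anomaly_series <- function(data, reference = c("initial", "mean")) {
  reference <- match.arg(reference)
  stopifnot("year" %in% names(data), nrow(data) > 0)
  out <- tibble::as_tibble(data)
  vars <- setdiff(names(out)[vapply(out, is.numeric, logical(1))], "year")
  for (v in vars) {
    ref <- if (reference == "initial") out[[v]][1] else mean(out[[v]])
    out[[v]] <- out[[v]] - ref
  }
  out
}
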