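#' Generate a random balanced food web
#'
#' Draws a cascade-ordered web (predators eat strictly lower-indexed living
#' groups, and detritus) with parameters from plausible ranges, then sizes
#' biomasses so that every ecotrophic efficiency stays below `ee_cap`. The
#' construction guarantees mass balance: [check_mass_balance()] residuals
#' are zero at machine precision after [solve_missing_ee()].
#'
#' @param n_groups Total number of groups including detritus.
#' @param n_producers Number of producers (>= 1).
#' @param n_detritus Number of detritus pools (>= 1).
#' @param connectance Probability of each permissible trophic link.
#' @param seed Integer seed; the same seed yields the identical web.
#' @param ee_cap Upper bound imposed on realized EE (default 0.9).
#' @return A balanced [food_web()] with all EE filled in.
#' @export
make_random_web <- function(n_groups = 10, n_producers = 2, n_detritus = 1,
                            connectance = 0.3, seed = 1, ee_cap = 0.9) {
  stopifnot(
    n_producers >= 1, n_detritus >= 1,
    connectance > 0, connectance <= 1,
    n_groups >= n_producers + n_detritus + 1
  )
  with_local_seed(seed, {
    n_cons <- n_groups - n_producers - n_detritus
    nm <- c(
      sprintf("prod%02d", seq_len(n_producers)),
      sprintf("cons%02d", seq_len(n_cons)),
      sprintf("detritus%02d", seq_len(n_detritus))
    )
    role <- c(
      rep("producer", n_producers), rep("consumer", n_cons),
      rep("detritus", n_detritus)
    )
    n_liv <- n_producers + n_cons
    cons_idx <- n_producers + seq_len(n_cons)
    det_idx <- n_liv + seq_len(n_detritus)

    # rates: consumption declines up the cascade, growth efficiency moderate
    QB <- numeric(n_groups)
    QB[cons_idx] <- exp(stats::runif(n_cons, log(3), log(30))) *
      0.85^seq_len(n_cons)
    gge <- stats::runif(n_groups, 0.15, 0.35)
    PB <- numeric(n_groups)
    PB[role == "producer"] <- stats::runif(n_producers, 20, 120)
    PB[cons_idx] <- gge[cons_idx] * QB[cons_idx]

    # cascade diets: prey must be lower-indexed living groups or detritus
    diet <- list()
    for (j in cons_idx) {
      prey_pool <- c(seq_len(j - 1L), det_idx)
      eats <- stats::runif(length(prey_pool)) < connectance
      if (!any(eats)) eats[sample.int(length(prey_pool), 1)] <- TRUE
      w <- stats::runif(sum(eats), 0.2, 1)
      diet[[length(diet) + 1]] <- tibble::tibble(
        predator = nm[j], prey = nm[prey_pool[eats]], proportion = w / sum(w)
      )
    }
    diet <- dplyr::bind_rows(diet)

    # size biomasses top-down so realized EE stays below the cap
    B <- numeric(n_groups)
    B[role == "producer"] <- stats::runif(n_producers, 2, 15)
    B[cons_idx] <- exp(stats::runif(n_cons, log(0.05), log(2)))
    B[det_idx] <- stats::runif(n_detritus, 5, 40)
    D <- matrix(0, n_groups + 1, n_groups, dimnames = list(c(nm, "import"), nm))
    D[cbind(diet$prey, diet$predator)] <- diet$proportion
    ee_target <- stats::runif(n_groups, 0.4, ee_cap)
    for (i in rev(seq_len(n_liv))) {
      higher <- seq_len(n_groups) > i
      pred_i <- sum(B[higher] * QB[higher] * D[i, higher])
      need <- pred_i / (ee_target[i] * PB[i])
      if (is.finite(need) && need > B[i]) B[i] <- need
    }

    web <- food_web(
      groups = tibble::tibble(
        name = nm, role = role, B = B, PB = PB, QB = QB,
        EE = NA_real_, GS = ifelse(role == "consumer", 0.2, 0)
      ),
      diet = diet
    )
    solve_missing_ee(web)
  })
}

#' Baltic-like 21-group food-web fixture
#'
#' A synthetic stand-in for a Central Baltic food web: 21 functional groups
#' (2 producers, 2 detritus pools, copepod and benthos groups, multi-stanza
#' sprat, herring and cod, and seals), three fleets (cod, sprat, herring)
#' and stanza graduation links (cod larvae -> juvenile -> small -> adult;
#' juvenile -> adult for sprat and herring).
#'
#' All parameter values are plausible synthetic placeholders shaped like an
#' Ecopath basic-input table — they are NOT a published calibration. The
#' web is balanced by construction (biomasses sized so every EE lies in
#' \[0, 1\]) and the companion [dynamic_params()] give an exact equilibrium
#' under neutral forcing.
#'
#' @return A list with elements `web` (a balanced [food_web()]) and
#'   `params` (a [dynamic_params()] with the stanza links).
#' @export
make_baltic_fixture <- function() {
  nm <- c(
    "Cyanobacteria", "Phytoplankton", "Microzooplankton", "Temora sp.",
    "Acartia sp.", "Pseudocalanus sp.", "Mesozooplankton", "Mysids",
    "Meiozoobenthos", "Macrozoobenthos", "Juvenile Sprat", "Adult Sprat",
    "Juvenile Herring", "Adult Herring", "Cod larvae", "Juvenile Cod",
    "Small Cod", "Adult Cod", "Seals", "Detritus (s)", "Detritus (w)"
  )
  role <- c(
    "producer", "producer", rep("consumer", 17), "detritus", "detritus"
  )
  # baseline biomass guesses (t/km2); sized up below where predation demands
  B <- c(
    2, 8, 1.5, 1.2, 1.0, 1.4, 1.0, 0.8, 1.5, 12,
    1.5, 6, 1.0, 4, 0.05, 0.3, 1.0, 2.5, 0.02, 50, 30
  )
  QB <- c(
    0, 0, 100, 45, 45, 40, 40, 12, 10, 6,
    12, 6, 10, 5, 30, 8, 4, 3.5, 15, 0, 0
  )
  gge <- c(
    NA, NA, 0.30, 0.30, 0.30, 0.30, 0.30, 0.25, 0.25, 0.25,
    0.22, 0.18, 0.22, 0.18, 0.20, 0.22, 0.20, 0.25, 0.04, NA, NA
  )
  PB <- ifelse(is.na(gge), 0, gge * QB)
  PB[1] <- 60   # cyanobacteria
  PB[2] <- 110  # phytoplankton
  GS <- ifelse(role == "consumer", 0.2, 0)
  GS[19] <- 0.15

  dd <- function(predator, ...) {
    kv <- c(...)
    tibble::tibble(
      predator = predator, prey = names(kv), proportion = unname(kv)
    )
  }
  diet <- dplyr::bind_rows(
    dd("Microzooplankton",
      "Phytoplankton" = 0.55, "Cyanobacteria" = 0.15, "Detritus (w)" = 0.30
    ),
    dd("Temora sp.",
      "Phytoplankton" = 0.55, "Microzooplankton" = 0.30, "Cyanobacteria" = 0.05,
      "Detritus (w)" = 0.10
    ),
    dd("Acartia sp.",
      "Phytoplankton" = 0.50, "Microzooplankton" = 0.35, "Cyanobacteria" = 0.10,
      "Detritus (w)" = 0.05
    ),
    dd("Pseudocalanus sp.",
      "Phytoplankton" = 0.60, "Microzooplankton" = 0.25, "Detritus (w)" = 0.15
    ),
    dd("Mesozooplankton",
      "Phytoplankton" = 0.45, "Microzooplankton" = 0.35, "Detritus (w)" = 0.20
    ),
    dd("Mysids",
      "Temora sp." = 0.15, "Acartia sp." = 0.10, "Pseudocalanus sp." = 0.15,
      "Mesozooplankton" = 0.20, "Detritus (s)" = 0.30, "Detritus (w)" = 0.10
    ),
    dd("Meiozoobenthos", "Detritus (s)" = 0.85, "Detritus (w)" = 0.15),
    dd("Macrozoobenthos",
      "Meiozoobenthos" = 0.15, "Detritus (s)" = 0.70, "Detritus (w)" = 0.15
    ),
    dd("Juvenile Sprat",
      "Temora sp." = 0.25, "Acartia sp." = 0.35, "Pseudocalanus sp." = 0.15,
      "Mesozooplankton" = 0.25
    ),
    dd("Adult Sprat",
      "Temora sp." = 0.30, "Acartia sp." = 0.25, "Pseudocalanus sp." = 0.25,
      "Mesozooplankton" = 0.20
    ),
    dd("Juvenile Herring",
      "Temora sp." = 0.20, "Acartia sp." = 0.25, "Pseudocalanus sp." = 0.25,
      "Mesozooplankton" = 0.20, "Mysids" = 0.10
    ),
    dd("Adult Herring",
      "Temora sp." = 0.15, "Acartia sp." = 0.10, "Pseudocalanus sp." = 0.25,
      "Mesozooplankton" = 0.15, "Mysids" = 0.20, "Macrozoobenthos" = 0.15
    ),
    dd("Cod larvae",
      "Temora sp." = 0.30, "Acartia sp." = 0.30, "Pseudocalanus sp." = 0.30,
      "Microzooplankton" = 0.10
    ),
    dd("Juvenile Cod",
      "Mesozooplankton" = 0.15, "Mysids" = 0.30, "Macrozoobenthos" = 0.40,
      "Meiozoobenthos" = 0.15
    ),
    dd("Small Cod",
      "Mysids" = 0.10, "Macrozoobenthos" = 0.35, "Juvenile Sprat" = 0.20,
      "Juvenile Herring" = 0.15, "Adult Sprat" = 0.15, "import" = 0.05
    ),
    dd("Adult Cod",
      "Adult Sprat" = 0.35, "Adult Herring" = 0.25, "Juvenile Sprat" = 0.10,
      "Juvenile Herring" = 0.10, "Macrozoobenthos" = 0.15, "Small Cod" = 0.05
    ),
    dd("Seals",
      "Adult Herring" = 0.30, "Adult Cod" = 0.25, "Adult Sprat" = 0.25,
      "Small Cod" = 0.10, "import" = 0.10
    )
  )
  # note: "Small Cod" appears as prey of Adult Cod — cascade order holds
  # (prey index 17 < predator index 18), so sizing remains single-pass

  # fishing mortalities (1/yr) and fleet mapping
  F0 <- stats::setNames(numeric(21), nm)
  F0[c("Juvenile Sprat", "Adult Sprat")] <- c(0.10, 0.35)
  F0[c("Juvenile Herring", "Adult Herring")] <- c(0.08, 0.25)
  F0[c("Small Cod", "Adult Cod")] <- c(0.20, 0.45)
  fleet_of <- c(
    "Juvenile Sprat" = "sprat", "Adult Sprat" = "sprat",
    "Juvenile Herring" = "herring", "Adult Herring" = "herring",
    "Small Cod" = "cod", "Adult Cod" = "cod"
  )

  # stanza graduation rates (1/yr); the EE cap below leaves room for them
  grad <- stats::setNames(numeric(21), nm)
  grad[c(
    "Cod larvae", "Juvenile Cod", "Small Cod", "Juvenile Sprat",
    "Juvenile Herring"
  )] <- c(2.0, 0.6, 0.35, 0.45, 0.40)

  # size biomasses so realized EE (predation + catch) stays under a cap
  # that reserves (graduation rate)/PB plus a safety margin, keeping the
  # back-solved background mortality non-negative
  ee_cap <- 0.85
  D <- matrix(0, 22, 21, dimnames = list(c(nm, "import"), nm))
  D[cbind(diet$prey, diet$predator)] <- diet$proportion
  for (i in rev(which(role != "detritus"))) {
    higher <- seq_len(21) > i
    pred_i <- sum(B[higher] * QB[higher] * D[i, higher])
    f_share <- F0[i] / PB[i]
    cap_i <- ee_cap - grad[i] / PB[i] - 0.05
    if (f_share >= cap_i) stop("fixture F exceeds the EE cap")
    need <- pred_i / ((cap_i - f_share) * PB[i])
    if (need > B[i]) B[i] <- need
  }
  landings <- tibble::tibble(
    group = names(fleet_of), fleet = unname(fleet_of),
    landings = unname(F0[names(fleet_of)] * B[match(names(fleet_of), nm)])
  )

  web <- food_web(
    groups = tibble::tibble(
      name = nm, role = role, B = B, PB = PB, QB = QB, EE = NA_real_,
      GS = GS, detritus_share = ifelse(role == "detritus", 0.5, NA_real_)
    ),
    diet = diet, landings = landings, fleets = c("cod", "sprat", "herring")
  )
  web <- solve_missing_ee(web)

  params <- dynamic_params(
    v = 2,
    stanza_links = tibble::tibble(
      from = c(
        "Cod larvae", "Juvenile Cod", "Small Cod", "Juvenile Sprat",
        "Juvenile Herring"
      ),
      to = c(
        "Juvenile Cod", "Small Cod", "Adult Cod", "Adult Sprat",
        "Adult Herring"
      ),
      rate = c(2.0, 0.6, 0.35, 0.45, 0.40)
    )
  )
  list(web = web, params = params)
}

#' Baseline forcing values of a calibrated model
#'
#' @param model A [dynamics_model()].
#' @return Named vector: `pp = 1` plus `F_<group>` baseline fishing
#'   mortalities for every fished group.
#' @export
forcing_baseline <- function(model) {
  f <- model$F0[model$F0 > 0]
  if (length(f) == 0) return(c(pp = 1))
  c(pp = 1, stats::setNames(f, paste0("F_", names(f))))
}

#' Neutral (baseline) forcing series
#'
#' @param model A [dynamics_model()].
#' @param years Calendar years.
#' @return Forcing tibble holding every series at its baseline.
#' @export
neutral_forcing <- function(model, years) {
  base <- forcing_baseline(model)
  out <- tibble::tibble(year = years)
  for (v in names(base)) out[[v]] <- base[[v]]
  out
}

#' Forcing scenario with planted step changes and AR(1) noise
#'
#' Builds an annual forcing table: each series follows a piecewise-constant
#' mean (steps planted at given years) plus stationary AR(1) noise,
#' emulating abrupt pressure changes over a multi-decadal study period.
#'
#' @param baseline Named vector of baseline levels (e.g. from
#'   [forcing_baseline()]), or a [dynamics_model()].
#' @param years Calendar years (default 1974:2006).
#' @param shifts Optional tibble `series`, `year`, `factor`: from `year`
#'   on, the series mean is `factor * baseline`. Multiple rows per series
#'   give multiple steps.
#' @param noise_sd Noise standard deviation as a fraction of the baseline
#'   level (scalar or named per series). 0 gives the exact step function.
#' @param ar1 AR(1) coefficient of the noise (|ar1| < 1).
#' @param seed Integer seed.
#' @return Forcing tibble `year` + one column per series, values floored
#'   at 0.
#' @export
make_forcing_scenario <- function(baseline, years = 1974:2006, shifts = NULL,
                                  noise_sd = 0, ar1 = 0.4, seed = 1) {
  if (inherits(baseline, "dynamics_model")) baseline <- forcing_baseline(baseline)
  stopifnot(abs(ar1) < 1, all(noise_sd >= 0))
  ny <- length(years)
  if (!is.null(shifts) &&
    (any(shifts$year < min(years)) || any(shifts$year > max(years)))) {
    stop("shift years must lie within the year span", call. = FALSE)
  }
  out <- tibble::tibble(year = years)
  with_local_seed(seed, {
    for (v in names(baseline)) {
      mu <- rep(baseline[[v]], ny)
      if (!is.null(shifts)) {
        sh <- shifts[shifts$series == v, , drop = FALSE]
        sh <- sh[order(sh$year), , drop = FALSE]
        for (r in seq_len(nrow(sh))) {
          mu[years >= sh$year[r]] <- sh$factor[r] * baseline[[v]]
        }
      }
      sd_v <- if (length(noise_sd) > 1) {
        if (v %in% names(noise_sd)) noise_sd[[v]] else 0
      } else {
        noise_sd
      }
      eps <- numeric(ny)
      if (sd_v > 0) {
        sigma <- sd_v * abs(baseline[[v]])
        eps[1] <- stats::rnorm(1, 0, sigma)
        innov_sd <- sigma * sqrt(1 - ar1^2)
        for (t in seq_len(ny - 1)) {
          eps[t + 1] <- ar1 * eps[t] + stats::rnorm(1, 0, innov_sd)
        }
      }
      out[[v]] <- pmax(mu + eps, 0)
    }
  })
  out
}

#' Two-block multivariate Gaussian test series
#'
#' A years-by-variables matrix with independent Gaussian noise and a mean
#' step of `mean_shift` in every variable after the first `n1` years — the
#' test bed for chronological clustering and PCA index recovery.
#'
#' @param n1,n2 Years in the first and second block.
#' @param mean_shift Mean difference between blocks (same units as
#'   `noise_sd`).
#' @param n_vars Number of variables.
#' @param noise_sd Noise standard deviation.
#' @param seed Integer seed.
#' @return Tibble `year` (1..n1+n2) plus `V1..Vk`.
#' @export
make_block_series <- function(n1 = 10, n2 = 10, mean_shift = 1, n_vars = 5,
                              noise_sd = 1, seed = 1) {
  with_local_seed(seed, {
    ny <- n1 + n2
    mu <- c(rep(0, n1), rep(mean_shift, n2))
    out <- tibble::tibble(year = seq_len(ny))
    for (k in seq_len(n_vars)) {
      out[[paste0("V", k)]] <- mu + stats::rnorm(ny, 0, noise_sd)
    }
    out
  })
}
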