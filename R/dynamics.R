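#' Dynamic simulation parameters
#'
#' Collects the knobs of the biomass dynamics on top of a static web:
#' per-link vulnerability multipliers for the foraging-arena consumption
#' closure, emigration/immigration, and fixed graduation rates linking life
#' stages (juvenile to adult) of multi-stanza species.
#'
#' @param v Default vulnerability multiplier (dimensionless, >= 1) applied
#'   to every trophic link. `v = 1` gives strongly donor-controlled (bottom
#'   -up) links; large `v` approaches Lotka-Volterra (top-down) dynamics.
#' @param v_table Optional tibble `prey`, `predator`, `v` overriding the
#'   default on specific links.
#' @param e Optional named vector of emigration rates (1/yr).
#' @param I Optional named vector of immigration flows (t/km2/yr).
#' @param stanza_links Optional tibble `from`, `to`, `rate` (1/yr) moving
#'   biomass from a juvenile to its adult group at a fixed graduation rate.
#' @param biomass_floor_frac Biomass floor, as a fraction of baseline
#'   biomass, applied during integration (with a warning).
#' @return An object of class `dynamic_params`.
#' @export
dynamic_params <- function(v = 2, v_table = NULL, e = NULL, I = NULL,
                           stanza_links = NULL, biomass_floor_frac = 1e-6) {
  if (v < 1) stop("vulnerability multipliers must be >= 1", call. = FALSE)
  if (!is.null(v_table) && any(v_table$v < 1)) {
    stop("vulnerability multipliers must be >= 1", call. = FALSE)
  }
  if (!is.null(stanza_links) && any(stanza_links$rate < 0)) {
    stop("graduation rates must be >= 0", call. = FALSE)
  }
  structure(
    list(
      v = v, v_table = v_table, e = e, I = I,
      stanza_links = stanza_links, biomass_floor_frac = biomass_floor_frac
    ),
    class = "dynamic_params"
  )
}

#' Calibrate a dynamic food-web model at its mass-balance baseline
#'
#' Back-solves every free rate constant so that the baseline state of the
#' static web is an exact equilibrium of the dynamics:
#' \itemize{
#'   \item foraging-arena search rates are solved per link so that consumption
#'     at baseline biomasses reproduces the Ecopath flows exactly, with the
#'     vulnerability multiplier setting the predator-saturation asymptote
#'     (twice the multiplier times the baseline flow);
#'   \item non-predation mortality `M0` is solved from the baseline budget
#'     (production − predation − fishing − migration − graduation);
#'   \item each detritus pool gets a burial (export) rate or a compensating
#'     import so its inflow and outflow balance.
#' }
#'
#' @param web A balanced [food_web()] (EE known).
#' @param params A [dynamic_params()].
#' @return An object of class `dynamics_model`.
#' @export
dynamics_model <- function(web, params = dynamic_params()) {
  g <- web$groups
  n <- n_groups(web)
  nm <- g$name
  if (anyNA(g$EE[g$role != "detritus"])) {
    stop("EE must be known; run solve_missing_ee() first", call. = FALSE)
  }
  B0 <- g$B
  Q0 <- consumption_flows(web) # (n+1) x n
  q_in0 <- colSums(Q0)
  pred0 <- rowSums(Q0)[seq_len(n)]

  gge <- rep(NA_real_, n)
  cons <- g$role == "consumer"
  gge[cons] <- g$PB[cons] / g$QB[cons]
  if (any(gge[cons] <= 0 | gge[cons] > 1)) {
    stop(
      "net growth efficiency PB/QB must lie in (0, 1]; offending: ",
      paste(nm[cons][gge[cons] <= 0 | gge[cons] > 1], collapse = ", "),
      call. = FALSE
    )
  }

  # per-link vulnerability multipliers
  V <- matrix(params$v, n, n, dimnames = list(nm, nm))
  if (!is.null(params$v_table)) {
    vt <- params$v_table
    V[cbind(vt$prey, vt$predator)] <- vt$v
  }

  # foraging arena: Q_ij = a v B_i B_j / (2 v + a B_j), with rate
  # v = 2 k Q0 / B_i0 (k the multiplier) so the predator-saturation
  # asymptote at baseline prey biomass is 2 k Q0
  Qint0 <- Q0[seq_len(n), , drop = FALSE]
  link <- Qint0 > 0
  vr <- a <- matrix(0, n, n, dimnames = list(nm, nm))
  for (idx in which(link)) {
    i <- (idx - 1L) %% n + 1L
    j <- (idx - 1L) %/% n + 1L
    k <- V[i, j]
    q0 <- Qint0[i, j]
    vr[i, j] <- 2 * k * q0 / B0[i]
    a[i, j] <- 4 * k * q0 / (B0[i] * B0[j] * (2 * k - 1))
  }
  # import feeding scales linearly with predator biomass
  q_imp_rate <- ifelse(B0 > 0, Q0[n + 1L, ] / B0, 0)

  yv <- catch_vector(web)
  F0 <- stats::setNames(ifelse(B0 > 0, yv / B0, 0), nm)
  fleet_share <- matrix(0, n, length(web$fleets),
    dimnames = list(nm, web$fleets)
  )
  if (nrow(web$landings) > 0 && length(web$fleets) > 0) {
    for (r in seq_len(nrow(web$landings))) {
      grp <- web$landings$group[r]
      fleet_share[grp, web$landings$fleet[r]] <-
        fleet_share[grp, web$landings$fleet[r]] + web$landings$landings[r]
    }
    tot <- rowSums(fleet_share)
    pos <- tot > 0
    fleet_share[pos, ] <- fleet_share[pos, , drop = FALSE] / tot[pos]
  }

  evec <- stats::setNames(numeric(n), nm)
  Ivec <- stats::setNames(numeric(n), nm)
  if (!is.null(params$e)) evec[names(params$e)] <- params$e
  if (!is.null(params$I)) Ivec[names(params$I)] <- params$I

  st <- params$stanza_links
  stanza <- if (is.null(st) || nrow(st) == 0) {
    list(from = integer(), to = integer(), rate = numeric())
  } else {
    list(
      from = match(st$from, nm), to = match(st$to, nm), rate = st$rate
    )
  }
  if (anyNA(stanza$from) || anyNA(stanza$to)) {
    stop("stanza links name unknown groups", call. = FALSE)
  }
  st_out0 <- st_in0 <- numeric(n)
  if (length(stanza$from) > 0) {
    flux0 <- stanza$rate * B0[stanza$from]
    for (k in seq_along(stanza$from)) {
      st_out0[stanza$from[k]] <- st_out0[stanza$from[k]] + flux0[k]
      st_in0[stanza$to[k]] <- st_in0[stanza$to[k]] + flux0[k]
    }
  }

  living <- g$role != "detritus"
  gain0 <- numeric(n)
  gain0[g$role == "producer"] <- (g$PB * B0)[g$role == "producer"]
  gain0[cons] <- (gge * q_in0)[cons]
  M0 <- numeric(n)
  for (i in which(living)) {
    if (B0[i] <= 0) next
    M0[i] <- (gain0[i] - pred0[i] + Ivec[i] + st_in0[i] - st_out0[i]) / B0[i] -
      F0[i] - evec[i]
  }
  if (any(M0 < -1e-9)) {
    stop(
      "calibration gives negative background mortality for: ",
      paste(nm[M0 < -1e-9], collapse = ", "),
      "; graduation/migration rates are inconsistent with the balance",
      call. = FALSE
    )
  }
  M0 <- pmax(M0, 0)

  det <- which(g$role == "detritus")
  shares <- g$detritus_share[det]
  to_det0 <- g$GS * q_in0 + M0 * B0
  to_det0[det] <- 0
  r_det <- I_det <- stats::setNames(numeric(length(det)), nm[det])
  for (k in seq_along(det)) {
    d <- det[k]
    inflow0 <- sum(to_det0) * shares[k]
    surplus <- inflow0 - pred0[d]
    if (surplus >= 0 && B0[d] > 0) {
      r_det[k] <- surplus / B0[d]
    } else {
      I_det[k] <- max(0, -surplus)
    }
  }

  structure(
    list(
      web = web, params = params, n = n, names = nm, role = g$role,
      B0 = B0, PB = g$PB, GS = g$GS, gge = gge, Q0 = Q0,
      link = link, a = a, vr = vr, q_imp_rate = q_imp_rate,
      F0 = F0, fleet_share = fleet_share, e = evec, I = Ivec,
      stanza = stanza, M0 = M0,
      det = det, det_shares = shares, r_det = r_det, I_det = I_det
    ),
    class = "dynamics_model"
  )
}

#' @export
print.dynamics_model <- function(x, ...) {
  cat(
    "<dynamics_model> ", x$n, " groups, ",
    sum(x$link), " trophic links, ",
    length(x$stanza$from), " stanza links\n",
    sep = ""
  )
  invisible(x)
}

#' Foraging-arena consumption matrix
#'
#' Realized consumption flows at a given biomass state. Each trophic link
#' follows the foraging-arena saturation `Q = a v B_prey B_pred /
#' (2 v + a B_pred)`: increasing and concave in predator biomass and
#' bounded by a vulnerability-dependent asymptote. At the calibration
#' baseline the matrix reproduces the static web's flows exactly.
#'
#' @param model A [dynamics_model()].
#' @param B Biomass vector (t/km2), in group order.
#' @param pp Primary-production multiplier (unused here; producers do not
#'   consume) — accepted for interface symmetry.
#' @param cons_mult Optional per-predator multiplier (named or length-n
#'   vector) scaling the search rates of that predator's links
#'   (environmental forcing hook).
#' @return `(n + 1) x n` matrix of flows (last row = import), t/km2/yr.
#' @export
consumption_matrix <- function(model, B, pp = 1, cons_mult = NULL) {
  n <- model$n
  if (length(B) != n) stop("biomass vector has wrong length", call. = FALSE)
  if (any(B < 0)) stop("negative biomass", call. = FALSE)
  m <- rep(1, n)
  if (!is.null(cons_mult)) {
    if (!is.null(names(cons_mult))) {
      m[match(names(cons_mult), model$names)] <- cons_mult
    } else {
      m <- rep_len(cons_mult, n)
    }
  }
  A <- sweep(model$a, 2, m, `*`)
  num <- A * model$vr * outer(B, B)
  den <- 2 * model$vr + sweep(A, 2, B, `*`)
  Q <- matrix(0, n + 1L, n, dimnames = dimnames(model$Q0))
  Q[seq_len(n), ][model$link] <- (num / den)[model$link]
  Q[n + 1L, ] <- model$q_imp_rate * B * m
  Q
}

# forcing inputs for one year, resolved against the model baseline
resolve_forcing_row <- function(model, row) {
  nmcols <- names(row)
  Fv <- model$F0
  fcols <- nmcols[startsWith(nmcols, "F_")]
  if (length(fcols) > 0) {
    grp <- sub("^F_", "", fcols)
    hit <- match(grp, model$names)
    if (anyNA(hit)) {
      stop("forcing column(s) for unknown group: ",
        paste(fcols[is.na(hit)], collapse = ", "),
        call. = FALSE
      )
    }
    Fv[hit] <- as.numeric(row[fcols])
  }
  pp <- if ("pp" %in% nmcols) as.numeric(row[["pp"]]) else 1
  ccols <- nmcols[startsWith(nmcols, "cons_")]
  cons_mult <- NULL
  if (length(ccols) > 0) {
    cons_mult <- stats::setNames(
      as.numeric(row[ccols]), sub("^cons_", "", ccols)
    )
  }
  list(F = Fv, pp = pp, cons_mult = cons_mult)
}

#' Biomass derivative of the forced dynamics
#'
#' Net growth rate per group: assimilated consumption (scaled by the net
#' growth efficiency) or primary production, minus predation, fishing,
#' background mortality and net migration, plus stanza graduation fluxes.
#' Detritus pools follow explicit inflow − outflow bookkeeping.
#'
#' @param model A [dynamics_model()].
#' @param B Biomass state vector (t/km2).
#' @param F Fishing mortality per group (1/yr); defaults to baseline.
#' @param pp Primary production multiplier (1 = baseline).
#' @param cons_mult Optional consumption multipliers, see
#'   [consumption_matrix()].
#' @return dB/dt per group, t/km2/yr.
#' @export
biomass_derivative <- function(model, B, F = NULL, pp = 1, cons_mult = NULL) {
  n <- model$n
  if (is.null(F)) F <- model$F0
  Q <- consumption_matrix(model, B, pp, cons_mult)
  q_in <- colSums(Q)
  pred <- rowSums(Q[seq_len(n), , drop = FALSE])

  gain <- numeric(n)
  prodr <- model$role == "producer"
  consr <- model$role == "consumer"
  gain[prodr] <- model$PB[prodr] * B[prodr] * pp
  gain[consr] <- model$gge[consr] * q_in[consr]

  st_in <- st_out <- numeric(n)
  if (length(model$stanza$from) > 0) {
    flux <- model$stanza$rate * B[model$stanza$from]
    for (k in seq_along(flux)) {
      st_out[model$stanza$from[k]] <- st_out[model$stanza$from[k]] + flux[k]
      st_in[model$stanza$to[k]] <- st_in[model$stanza$to[k]] + flux[k]
    }
  }

  dB <- gain - pred - (model$M0 + F + model$e) * B + model$I + st_in - st_out

  # detritus pools: inflow - outflow bookkeeping
  to_det <- model$GS * q_in + model$M0 * B
  to_det[model$det] <- 0
  tot_in <- sum(to_det)
  for (k in seq_along(model$det)) {
    d <- model$det[k]
    dB[d] <- tot_in * model$det_shares[k] - pred[d] - model$r_det[k] * B[d] +
      model$I_det[k] - F[d] * B[d]
  }
  dB
}

#' Simulate biomass dynamics under annual forcing
#'
#' Fixed-step 4th-order Runge-Kutta integration of the biomass dynamics,
#' with forcing held constant within each calendar year. Annual outputs
#' (mean biomass, accumulated consumption, production and catch) are
#' integrated with Simpson's rule over the within-year sub-steps.
#'
#' @param model A [dynamics_model()].
#' @param forcing Forcing tibble with a `year` column and any of: `pp`
#'   (primary production multiplier), `F_<group>` (absolute fishing
#'   mortality, 1/yr), `cons_<group>` (consumption multiplier on a
#'   predator's links). Missing columns stay at baseline.
#' @param dt Integration step, years (default monthly; must be <= 1/12).
#' @return An object of class `trajectory`: yearly biomass `B`
#'   (years x groups), catches `Y`, production `prod`, consumption flow
#'   matrices `Q` (list), stanza fluxes, and the model.
#' @export
simulate_foodweb <- function(model, forcing, dt = 1 / 12) {
  if (dt > 1 / 12 + 1e-12) stop("dt must be at most 1/12 yr", call. = FALSE)
  stopifnot(is.data.frame(forcing), "year" %in% names(forcing))
  n <- model$n
  years <- forcing$year
  ny <- length(years)
  spy <- ceiling(1 / dt)
  # explicit RK4 needs steps shorter than the fastest turnover time;
  # enforce a stability floor of ~2 sub-steps per unit loss rate
  q_in0 <- colSums(model$Q0)
  turnover <- ifelse(model$B0 > 0,
    (pmax(rowSums(model$Q0[seq_len(n), , drop = FALSE]), q_in0)) / model$B0,
    0
  ) + model$M0 + model$F0 + model$e
  turnover[model$role == "producer"] <-
    turnover[model$role == "producer"] + model$PB[model$role == "producer"]
  for (k in seq_along(model$det)) {
    turnover[model$det[k]] <- turnover[model$det[k]] + model$r_det[k]
  }
  spy <- max(spy, ceiling(2 * max(turnover)))
  if (spy %% 2 == 1) spy <- spy + 1L
  h <- 1 / spy
  wts <- c(1, rep(c(4, 2), length.out = spy - 1), 1) * (h / 3)

  floor_B <- pmax(model$params$biomass_floor_frac * model$B0, 1e-12)
  B <- model$B0
  Bout <- matrix(0, ny, n, dimnames = list(years, model$names))
  Yout <- matrix(0, ny, n, dimnames = list(years, model$names))
  Pout <- matrix(0, ny, n, dimnames = list(years, model$names))
  Qout <- vector("list", ny)
  nst <- length(model$stanza$from)
  Sout <- matrix(0, ny, nst)
  floored <- character()

  for (y in seq_len(ny)) {
    fc <- resolve_forcing_row(model, forcing[y, , drop = FALSE])
    deriv <- function(b) {
      biomass_derivative(model, b, F = fc$F, pp = fc$pp,
        cons_mult = fc$cons_mult
      )
    }
    Qacc <- matrix(0, n + 1L, n)
    Bacc <- Yacc <- Pacc <- numeric(n)
    Sacc <- numeric(nst)
    snapshot <- function(b, w) {
      Qs <- consumption_matrix(model, b, fc$pp, fc$cons_mult)
      Qacc <<- Qacc + w * Qs
      Bacc <<- Bacc + w * b
      Yacc <<- Yacc + w * fc$F * b
      pr <- numeric(n)
      prodr <- model$role == "producer"
      pr[prodr] <- model$PB[prodr] * b[prodr] * fc$pp
      consr <- model$role == "consumer"
      pr[consr] <- model$gge[consr] * colSums(Qs)[consr]
      Pacc <<- Pacc + w * pr
      if (nst > 0) Sacc <<- Sacc + w * model$stanza$rate * b[model$stanza$from]
    }
    snapshot(B, wts[1])
    for (s in seq_len(spy)) {
      k1 <- deriv(B)
      k2 <- deriv(pmax(B + h / 2 * k1, 0))
      k3 <- deriv(pmax(B + h / 2 * k2, 0))
      k4 <- deriv(pmax(B + h * k3, 0))
      B <- B + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (any(!is.finite(B))) {
        stop(
          "non-finite biomass for group '",
          model$names[which(!is.finite(B))[1]],
          "' in year ", years[y], ", sub-step ", s,
          call. = FALSE
        )
      }
      low <- B < floor_B
      if (any(low)) {
        floored <- union(floored, model$names[low])
        B[low] <- floor_B[low]
      }
      snapshot(B, wts[s + 1])
    }
    Bout[y, ] <- Bacc
    Yout[y, ] <- Yacc
    Pout[y, ] <- Pacc
    Qout[[y]] <- Qacc
    if (nst > 0) Sout[y, ] <- Sacc
  }
  if (length(floored) > 0) {
    warning(
      "biomass floored at epsilon for: ", paste(floored, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      years = years, B = Bout, Y = Yout, prod = Pout, Q = Qout,
      stanza_flux = Sout, model = model, forcing = forcing
    ),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(
    "<trajectory> ", length(x$years), " years (", min(x$years), "-",
    max(x$years), "), ", ncol(x$B), " groups\n",
    sep = ""
  )
  invisible(x)
}

#' Yearly biomass of a trajectory in long form
#'
#' @param x A `trajectory` from [simulate_foodweb()].
#' @param ... Unused.
#' @return Tibble `year`, `group`, `biomass`, `catch`.
#' @exportS3Method generics::tidy
tidy.trajectory <- function(x, ...) {
  b <- tibble::as_tibble(x$B)
  b$year <- x$years
  out <- tidyr::pivot_longer(b, -"year",
    names_to = "group", values_to = "biomass"
  )
  yc <- tibble::as_tibble(x$Y)
  yc$year <- x$years
  yl <- tidyr::pivot_longer(yc, -"year", names_to = "group", values_to = "catch")
  dplyr::left_join(out, yl, by = c("year", "group"))
}

#' Yearly biomass in wide form
#'
#' @param traj A `trajectory`.
#' @return Tibble with a `year` column and one column per group.
#' @export
biomass_series <- function(traj) {
  out <- tibble::as_tibble(traj$B)
  dplyr::bind_cols(tibble::tibble(year = traj$years), out)
}

#' Annual flow-network snapshots of a simulation
#'
#' Builds one [flow_network()] per simulated year from that year's
#' accumulated flows, with the same compartment layout every year:
#' consumption and import feeding from the integrated consumption matrix,
#' primary production as import, unassimilated food and background
#' mortality routed to the detritus pools, respiration as the assimilation
#' residual, catches and emigration as export, and the calibrated detrital
#' burial/import closing the detritus budget. Stanza graduation is included
#' as an explicit internal flow so the mass budget stays closed.
#'
#' @param traj A `trajectory` from [simulate_foodweb()].
#' @param balance_tol Steady-state warning tolerance passed to
#'   [flow_network()] (transient years are legitimately out of balance).
#' @param quiet Suppress balance warnings (default TRUE).
#' @return Named list of [flow_network()]s, one per year.
#' @export
annual_flow_snapshots <- function(traj, balance_tol = 1e-3, quiet = TRUE) {
  model <- traj$model
  n <- model$n
  nm <- model$names
  labels <- c(nm, "import", "export", "respiration")
  i_imp <- n + 1L; i_exp <- n + 2L; i_res <- n + 3L
  out <- vector("list", length(traj$years))
  names(out) <- traj$years
  for (y in seq_along(traj$years)) {
    Qy <- traj$Q[[y]]
    By <- traj$B[y, ]
    Yy <- traj$Y[y, ]
    Py <- traj$prod[y, ]
    q_in <- colSums(Qy)
    T <- matrix(0, n + 3L, n + 3L, dimnames = list(labels, labels))
    T[seq_len(n), seq_len(n)] <- Qy[seq_len(n), ]
    T[i_imp, seq_len(n)] <- Qy[n + 1L, ]
    prodr <- which(model$role == "producer")
    consr <- model$role == "consumer"
    T[i_imp, prodr] <- T[i_imp, prodr] + Py[prodr]
    # stanza graduation as internal flows
    if (length(model$stanza$from) > 0) {
      for (k in seq_along(model$stanza$from)) {
        T[model$stanza$from[k], model$stanza$to[k]] <-
          T[model$stanza$from[k], model$stanza$to[k]] + traj$stanza_flux[y, k]
      }
    }
    resp <- numeric(n)
    resp[consr] <- pmax((1 - model$GS[consr]) * q_in[consr] - Py[consr], 0)
    to_det <- model$GS * q_in + model$M0 * By
    to_det[model$det] <- 0
    for (k in seq_along(model$det)) {
      d <- model$det[k]
      add <- to_det * model$det_shares[k]
      add[d] <- 0
      T[seq_len(n), d] <- T[seq_len(n), d] + add
      T[d, i_exp] <- T[d, i_exp] + model$r_det[k] * By[d]
      T[i_imp, d] <- T[i_imp, d] + model$I_det[k]
    }
    T[seq_len(n), i_res] <- resp
    T[seq_len(n), i_exp] <- T[seq_len(n), i_exp] + Yy + model$e * By
    T[i_imp, seq_len(n)] <- T[i_imp, seq_len(n)] + model$I
    out[[y]] <- flow_network(
      T = T, labels = labels, role = model$role, biomass = unname(By),
      production = unname(Py), catch = unname(Yy),
      balance_tol = balance_tol, quiet = quiet
    )
  }
  out
}
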