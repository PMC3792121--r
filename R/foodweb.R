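#' Construct a mass-balanced food-web description
#'
#' A `food_web` bundles the static Ecopath-style description of a food web:
#' per-group rate parameters, the diet composition matrix in long form,
#' landings per fleet, and the routing of detrital flows between detritus
#' pools. It is the input to [check_mass_balance()], [solve_missing_ee()],
#' [trophic_levels()], [to_flow_network()] and the dynamic simulator.
#'
#' @param groups Data frame with one row per functional group and columns
#'   `name` (unique identifier), `role` (one of `"producer"`, `"consumer"`,
#'   `"detritus"`), `B` (biomass, t/km2 wet weight), `PB` (production/biomass,
#'   1/yr), `QB` (consumption/biomass, 1/yr; 0 for producers and detritus),
#'   `EE` (ecotrophic efficiency in \[0, 1\], `NA` if unknown), `GS`
#'   (unassimilated fraction of consumption in \[0, 1)). Detritus rows may
#'   carry a `detritus_share` column giving each pool's share of detrital
#'   inflow (shares sum to 1; a single pool defaults to 1).
#' @param diet Data frame with columns `predator`, `prey`, `proportion`.
#'   Diet fractions of each consumer must sum to 1; `prey` may be the
#'   special name `"import"` for food taken from outside the system.
#'   Producers and detritus have no diet rows.
#' @param landings Optional data frame with columns `group`, `fleet`,
#'   `landings` (t/km2/yr).
#' @param fleets Character vector of fleet names. Defaults to the fleets
#'   present in `landings`.
#'
#' @return An object of class `food_web`.
#' @examples
#' web <- food_web(
#'   groups = tibble::tibble(
#'     name = c("algae", "grazer"),
#'     role = c("producer", "consumer"),
#'     B = c(10, 1), PB = c(10, 10), QB = c(0, 50),
#'     EE = c(0.5, 0), GS = c(0, 0.2)
#'   ),
#'   diet = tibble::tibble(predator = "grazer", prey = "algae", proportion = 1)
#' )
#' check_mass_balance(web)
#' @export
food_web <- function(groups, diet = NULL, landings = NULL, fleets = NULL) {
  groups <- tibble::as_tibble(groups)
  required <- c("name", "role", "B", "PB", "QB", "EE", "GS")
  missing_cols <- setdiff(required, names(groups))
  if (length(missing_cols) > 0) {
    stop("`groups` is missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(groups$name)) {
    stop("group names must be unique", call. = FALSE)
  }
  if ("import" %in% groups$name) {
    stop('"import" is a reserved name and cannot be a group', call. = FALSE)
  }
  if (!all(groups$role %in% c("producer", "consumer", "detritus"))) {
    stop('`role` must be one of "producer", "consumer", "detritus"',
      call. = FALSE
    )
  }
  if (!any(groups$role == "detritus")) {
    stop("a food web needs at least one detritus group", call. = FALSE)
  }
  if (!"detritus_share" %in% names(groups)) groups$detritus_share <- NA_real_
  ndet <- sum(groups$role == "detritus")
  det <- groups$role == "detritus"
  if (all(is.na(groups$detritus_share[det]))) {
    groups$detritus_share[det] <- 1 / ndet
  }
  shares <- groups$detritus_share[det]
  if (anyNA(shares) || any(shares < 0) ||
    abs(sum(shares) - 1) > 1e-8) {
    stop("`detritus_share` values must be non-negative and sum to 1 over the detritus pools",
      call. = FALSE
    )
  }
  with(groups, {
    if (any(B < 0, na.rm = TRUE) || any(PB < 0, na.rm = TRUE) ||
      any(QB < 0, na.rm = TRUE)) {
      stop("B, PB and QB must be non-negative", call. = FALSE)
    }
  })
  if (any(groups$role == "consumer" & groups$QB <= 0)) {
    stop("consumers must have QB > 0", call. = FALSE)
  }
  if (any(groups$role != "consumer" & groups$QB != 0)) {
    stop("producers and detritus must have QB = 0", call. = FALSE)
  }
  if (any(groups$GS < 0 | groups$GS >= 1)) {
    stop("GS must lie in [0, 1)", call. = FALSE)
  }
  ee <- groups$EE
  if (any(ee[!is.na(ee)] < 0 | ee[!is.na(ee)] > 1 + 1e-9)) {
    stop("known EE values must lie in [0, 1]", call. = FALSE)
  }

  if (is.null(diet)) {
    diet <- tibble::tibble(
      predator = character(), prey = character(), proportion = numeric()
    )
  }
  diet <- tibble::as_tibble(diet)[, c("predator", "prey", "proportion")]
  diet <- diet[diet$proportion != 0, , drop = FALSE]
  bad_pred <- setdiff(diet$predator, groups$name)
  if (length(bad_pred) > 0) {
    stop("diet declares unknown predator(s): ", paste(bad_pred, collapse = ", "),
      call. = FALSE
    )
  }
  bad_prey <- setdiff(diet$prey, c(groups$name, "import"))
  if (length(bad_prey) > 0) {
    stop("diet declares unknown prey: ", paste(bad_prey, collapse = ", "),
      call. = FALSE
    )
  }
  non_consumer <- groups$name[groups$role != "consumer"]
  if (any(diet$predator %in% non_consumer)) {
    stop("only consumers may have diet entries", call. = FALSE)
  }
  if (any(diet$proportion < 0)) stop("diet proportions must be >= 0", call. = FALSE)
  sums <- tapply(diet$proportion, diet$predator, sum)
  consumers <- groups$name[groups$role == "consumer"]
  missing_diet <- setdiff(consumers, names(sums))
  if (length(missing_diet) > 0) {
    stop("consumer(s) without a diet: ", paste(missing_diet, collapse = ", "),
      call. = FALSE
    )
  }
  off <- abs(sums - 1) > 1e-6
  if (any(off)) {
    stop(
      "diet fractions must sum to 1 (including import); offending: ",
      paste(names(sums)[off], collapse = ", "),
      call. = FALSE
    )
  }

  if (is.null(landings)) {
    landings <- tibble::tibble(
      group = character(), fleet = character(), landings = numeric()
    )
  }
  landings <- tibble::as_tibble(landings)[, c("group", "fleet", "landings")]
  landings <- landings[landings$landings != 0, , drop = FALSE]
  bad_grp <- setdiff(landings$group, groups$name)
  if (length(bad_grp) > 0) {
    stop("landings declare unknown group(s): ", paste(bad_grp, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(landings$landings < 0)) stop("landings must be >= 0", call. = FALSE)
  if (is.null(fleets)) fleets <- sort(unique(landings$fleet))
  bad_fleet <- setdiff(landings$fleet, fleets)
  if (length(bad_fleet) > 0) {
    stop("landings declare unknown fleet(s): ", paste(bad_fleet, collapse = ", "),
      call. = FALSE
    )
  }

  structure(
    list(groups = groups, diet = diet, landings = landings, fleets = fleets),
    class = "food_web"
  )
}

#' @export
print.food_web <- function(x, ...) {
  cat(
    "<food_web> ", nrow(x$groups), " groups (",
    sum(x$groups$role == "producer"), " producers, ",
    sum(x$groups$role == "consumer"), " consumers, ",
    sum(x$groups$role == "detritus"), " detritus pools), ",
    length(x$fleets), " fleets\n",
    sep = ""
  )
  invisible(x)
}

n_groups <- function(web) nrow(web$groups)

group_names <- function(web) web$groups$name

#' Diet composition matrix
#'
#' @param web A [food_web()].
#' @return A numeric matrix with one row per prey (plus a final `"import"`
#'   row) and one column per group; entry is the diet fraction of the column
#'   predator on the row prey. Columns of non-consumers are zero.
#' @export
diet_matrix <- function(web) {
  nm <- group_names(web)
  D <- matrix(0, nrow = length(nm) + 1, ncol = length(nm),
    dimnames = list(c(nm, "import"), nm)
  )
  if (nrow(web$diet) > 0) {
    D[cbind(web$diet$prey, web$diet$predator)] <- web$diet$proportion
  }
  D
}

# (n+1) x n consumption matrix Q[i, j] = B_j * QB_j * diet fraction of j on i,
# final row = import. Optionally with an overridden biomass vector.
consumption_flows <- function(web, biomass = NULL) {
  g <- web$groups
  B <- if (is.null(biomass)) g$B else biomass
  D <- diet_matrix(web)
  sweep(D, 2, B * g$QB, `*`)
}

# Total catch per group, named vector.
catch_vector <- function(web) {
  y <- stats::setNames(numeric(n_groups(web)), group_names(web))
  if (nrow(web$landings) > 0) {
    tot <- tapply(web$landings$landings, web$landings$group, sum)
    y[names(tot)] <- tot
  }
  y
}

#' Check Ecopath mass balance
#'
#' For every living group, production allocated within the system
#' (predation by the web's consumers plus catch) is compared with the
#' production term `B * PB * EE`. A balanced web has zero residuals.
#'
#' @param web A [food_web()] with all EE values known.
#' @return A tibble with one row per living group and columns `group`,
#'   `production` (B*PB, t/km2/yr), `predation`, `catch`, `allocated`
#'   (predation + catch) and `residual` (allocated − B*PB*EE).
#' @export
check_mass_balance <- function(web) {
  g <- web$groups
  living <- g$role != "detritus"
  if (anyNA(g$EE[living])) {
    stop(
      "cannot check mass balance: EE unknown for ",
      paste(g$name[living][is.na(g$EE[living])], collapse = ", "),
      "; run solve_missing_ee() first",
      call. = FALSE
    )
  }
  Q <- consumption_flows(web)
  predation <- unname(rowSums(Q)[seq_len(n_groups(web))])
  catch <- unname(catch_vector(web))
  allocated <- predation + catch
  tibble::tibble(
    group = g$name[living],
    production = (g$B * g$PB)[living],
    predation = predation[living],
    catch = catch[living],
    allocated = allocated[living],
    residual = allocated[living] - (g$B * g$PB * g$EE)[living]
  )
}

#' Solve for missing ecotrophic efficiencies
#'
#' Fills unknown `EE` entries from the balance identity
#' `EE = (predation + catch) / (B * PB)`, the standard Ecopath closure when
#' biomasses and rates are known. Known EE entries are left untouched.
#'
#' @param web A [food_web()].
#' @param tol Numerical slack allowed above 1 before a group is declared
#'   unbalanced.
#' @return The web with all living-group EE values populated. Detritus EE
#'   is left `NA` (it has no production term).
#' @export
solve_missing_ee <- function(web, tol = 1e-9) {
  g <- web$groups
  Q <- consumption_flows(web)
  predation <- rowSums(Q)[seq_len(n_groups(web))]
  catch <- catch_vector(web)
  living <- g$role != "detritus"
  fill <- living & is.na(g$EE)
  if (any(fill)) {
    prod <- g$B * g$PB
    ee <- (predation + catch)[fill] / prod[fill]
    ee[(predation + catch)[fill] == 0] <- 0
    bad <- !is.finite(ee) | ee > 1 + tol
    if (any(bad)) {
      stop(
        "unbalanced web: predation + catch exceeds production for ",
        paste(g$name[fill][bad], collapse = ", "),
        call. = FALSE
      )
    }
    g$EE[fill] <- pmin(ee, 1)
  }
  web$groups <- g
  web
}

#' Trophic levels from the diet matrix
#'
#' Solves the linear system `TL_i = 1 + sum_j diet_ij * TL_j`, with
#' producers, detritus and imported food fixed at trophic level 1.
#'
#' @param web A [food_web()].
#' @return A tibble with columns `group` and `TL` (dimensionless, >= 1).
#' @export
trophic_levels <- function(web) {
  g <- web$groups
  n <- n_groups(web)
  D <- diet_matrix(web)
  # M[i, j]: fraction of consumer i's diet on living group j
  M <- t(D[seq_len(n), , drop = FALSE])
  b <- 1 + D["import", ] # imported food has trophic level 1
  fixed <- g$role != "consumer"
  M[fixed, ] <- 0
  b[fixed] <- 1
  A <- diag(n) - M
  tl <- tryCatch(
    solve(A, b),
    error = function(e) {
      stop("trophic level system is singular (degenerate cannibalistic diet)",
        call. = FALSE
      )
    }
  )
  tibble::tibble(group = g$name, TL = as.numeric(tl))
}

#' Convert a balanced food web to an annual flow network
#'
#' Performs the standard Ecopath flow bookkeeping: consumption flows
#' prey -> predator, unassimilated food and non-predation mortality to the
#' detritus pools (split by `detritus_share`), respiration as dissipation,
#' catches as export, primary production and import diet as imports, and a
#' balancing export (burial) or import for each detritus pool.
#'
#' @param web A balanced [food_web()] (all EE known, residuals ~ 0).
#' @param biomass Optional named or positional biomass vector overriding the
#'   web's biomasses (used for sensitivity runs; flows are recomputed from
#'   the bookkeeping identities, so the result may be out of balance).
#' @param balance_tol Relative tolerance (fraction of total system
#'   throughput) above which a per-compartment imbalance triggers a warning.
#' @param quiet Suppress warnings about floored respiration/mortality.
#' @return A [flow_network()].
#' @export
to_flow_network <- function(web, biomass = NULL, balance_tol = 1e-6,
                            quiet = FALSE) {
  g <- web$groups
  n <- n_groups(web)
  nm <- g$name
  if (anyNA(g$EE[g$role != "detritus"])) {
    stop("EE must be known for all living groups; run solve_missing_ee()",
      call. = FALSE
    )
  }
  B <- g$B
  if (!is.null(biomass)) {
    if (!is.null(names(biomass))) biomass <- biomass[nm]
    stopifnot(length(biomass) == n)
    B <- as.numeric(biomass)
  }

  Q <- consumption_flows(web, B) # (n+1) x n, last row import
  q_in <- colSums(Q)
  predation <- rowSums(Q)[seq_len(n)]
  catch <- catch_vector(web)
  production <- B * g$PB
  production[g$role == "detritus"] <- 0

  i_imp <- n + 1L
  i_exp <- n + 2L
  i_res <- n + 3L
  labels <- c(nm, "import", "export", "respiration")
  T <- matrix(0, n + 3, n + 3, dimnames = list(labels, labels))
  T[seq_len(n), seq_len(n)] <- Q[seq_len(n), ]
  T[i_imp, seq_len(n)] <- Q[n + 1, ]

  living <- g$role != "detritus"
  floored <- character()

  # primary production enters the producers as an import
  prod_rows <- which(g$role == "producer")
  T[i_imp, prod_rows] <- T[i_imp, prod_rows] + production[prod_rows]

  # non-predation mortality (to detritus) and respiration
  other_mort <- numeric(n)
  respiration <- numeric(n)
  for (i in which(living)) {
    om <- production[i] - predation[i] - catch[i]
    if (om < 0) {
      if (om < -1e-9 * max(production[i], 1e-12)) floored <- c(floored, nm[i])
      om <- 0
    }
    other_mort[i] <- om
    if (g$role[i] == "consumer") {
      resp <- (1 - g$GS[i]) * q_in[i] - production[i]
      if (resp < 0) {
        floored <- c(floored, nm[i])
        resp <- 0
      }
      respiration[i] <- resp
    }
  }
  unassim <- g$GS * q_in
  unassim[!living] <- 0

  det_rows <- which(g$role == "detritus")
  shares <- g$detritus_share[det_rows]
  to_det <- other_mort + unassim
  for (k in seq_along(det_rows)) {
    d <- det_rows[k]
    inflow_d <- to_det * shares[k]
    inflow_d[d] <- 0 # a pool does not feed itself
    T[seq_len(n), d] <- T[seq_len(n), d] + inflow_d
  }

  T[seq_len(n), i_res] <- respiration
  T[seq_len(n), i_exp] <- catch

  # balance the detritus pools against export (burial) or import
  for (d in det_rows) {
    inflow <- sum(T[seq_len(n + 1), d])
    outflow <- sum(T[d, ])
    surplus <- inflow - outflow
    if (surplus >= 0) {
      T[d, i_exp] <- T[d, i_exp] + surplus
    } else {
      T[i_imp, d] <- T[i_imp, d] - surplus
    }
  }

  if (!quiet && length(floored) > 0) {
    warning(
      "negative respiration/mortality floored at 0 (web flagged unbalanced) for: ",
      paste(unique(floored), collapse = ", "),
      call. = FALSE
    )
  }

  flow_network(
    T = T, labels = labels, role = g$role, biomass = B,
    production = production, catch = catch,
    balance_tol = balance_tol, quiet = quiet
  )
}
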