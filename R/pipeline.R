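#' Run the full regime-shift analysis pipeline
#'
#' Executes the three analyses of the study design end to end:
#' \enumerate{
#'   \item forcing analysis: STARS per forcing series, PCA pressure index
#'     (PC1) with STARS on its scores, chronological clustering, traffic
#'     light table;
#'   \item biomass analysis: simulate the web under the forcing, then
#'     STARS (long cut-off), PCA state index, chronological clustering and
#'     traffic light on the modelled biomasses;
#'   \item indicator analysis: annual flow networks, the 15 ecosystem/ENA
#'     indicators, STARS and chronological clustering on the indicator
#'     series, and per-regime coefficients of variation.
#' }
#'
#' @param web A balanced [food_web()].
#' @param forcing Forcing tibble (see [simulate_foodweb()]).
#' @param params A [dynamic_params()].
#' @param stars_cutoff_fast Cut-off length for forcing and indicator
#'   series (default 5 yr).
#' @param stars_cutoff_biomass Cut-off length for biomass series (default
#'   10 yr).
#' @param stars_alpha,stars_huber STARS parameters.
#' @param cc_alpha,cc_connectedness,cc_n_perm Chronological clustering
#'   parameters.
#' @param cv_periods List of `c(start, end)` periods (closed intervals)
#'   for the coefficient of variation table; defaults to the two halves of
#'   the span split before the median year plus the whole span (for
#'   1974-2006: 1974-1989, 1990-2006, 1974-2006).
#' @param biomass_exclude Group names excluded from the biomass statistics
#'   (defaults to seal and detritus groups, which are forcing-like or
#'   redundant with primary production).
#' @param seed Single seed governing every stochastic stage.
#' @param out_dir Optional output directory; when given, all tables are
#'   written as delimited text plus a JSON manifest.
#' @return A list of class `ena_pipeline` with elements `forcing`,
#'   `biomass`, `indicators` (each holding the relevant series, STARS,
#'   PCA, CC and traffic-light results), `trajectory`, `networks` and
#'   `config`.
#' @export
run_pipeline <- function(web, forcing, params = dynamic_params(),
                         stars_cutoff_fast = 5, stars_cutoff_biomass = 10,
                         stars_alpha = 0.05, stars_huber = 3,
                         cc_alpha = 0.01, cc_connectedness = 0.5,
                         cc_n_perm = 999,
                         cv_periods = NULL,
                         biomass_exclude = NULL,
                         seed = 1, out_dir = NULL) {
  years <- forcing$year
  if (is.null(cv_periods)) {
    mid <- floor(stats::median(years))
    cv_periods <- list(
      c(min(years), mid - 1), c(mid, max(years)), c(min(years), max(years))
    )
  }

  # --- analysis i: forcing -------------------------------------------------
  f_vars <- setdiff(names(forcing), "year")
  f_varying <- f_vars[vapply(
    f_vars, function(v) stats::sd(forcing[[v]]) > 0, logical(1)
  )]
  f_data <- forcing[c("year", f_varying)]
  f_anom <- anomaly_series(f_data)
  forcing_res <- list(
    data = f_data,
    shifts = detect_shifts(f_data,
      alpha = stars_alpha, cutoff = stars_cutoff_fast, huber = stars_huber
    )
  )
  if (length(f_varying) >= 2) {
    forcing_res$pca <- pca_index(f_anom)
    forcing_res$pc1_stars <- stars_on_scores(forcing_res$pca, 1,
      alpha = stars_alpha, cutoff = stars_cutoff_fast, huber = stars_huber
    )
    forcing_res$cc <- chronological_clustering(f_anom,
      alpha = cc_alpha, connectedness = cc_connectedness,
      n_perm = cc_n_perm, seed = seed
    )
    forcing_res$traffic_light <- traffic_light(f_data, forcing_res$pca)
  }

  # --- analysis ii: modelled biomass --------------------------------------
  model <- dynamics_model(web, params)
  traj <- simulate_foodweb(model, forcing)
  bio <- biomass_series(traj)
  if (is.null(biomass_exclude)) {
    biomass_exclude <- web$groups$name[
      web$groups$role == "detritus" |
        grepl("seal", web$groups$name, ignore.case = TRUE)
    ]
  }
  bio_stat <- bio[c("year", setdiff(names(bio), c("year", biomass_exclude)))]
  bio_varying <- names(bio_stat)[-1][vapply(
    names(bio_stat)[-1], function(v) stats::sd(bio_stat[[v]]) > 0, logical(1)
  )]
  biomass_res <- list(
    data = bio_stat,
    shifts = detect_shifts(bio_stat,
      alpha = stars_alpha, cutoff = stars_cutoff_biomass, huber = stars_huber
    )
  )
  if (length(bio_varying) >= 2) {
    bv <- bio_stat[c("year", bio_varying)]
    biomass_res$pca <- pca_index(bv)
    biomass_res$pc1_stars <- stars_on_scores(biomass_res$pca, 1,
      alpha = stars_alpha, cutoff = stars_cutoff_biomass, huber = stars_huber
    )
    biomass_res$cc <- chronological_clustering(bv,
      alpha = cc_alpha, connectedness = cc_connectedness,
      n_perm = cc_n_perm, seed = seed + 1L
    )
    biomass_res$traffic_light <- traffic_light(bv, biomass_res$pca)
  }

  # --- analysis iii: ecosystem indicators ---------------------------------
  nets <- annual_flow_snapshots(traj)
  ind <- indicator_series(nets, years)
  ind_stat <- ind[c(
    "year", "TST", "AC_ratio", "R_pct_C", "AMI", "H", "FCI", "PCI", "MPL",
    "PFD", "TPP_TR", "ToTP_ToTB", "TotC", "PPR_PP", "mTLc", "KemptonQ"
  )]
  ind_varying <- names(ind_stat)[-1][vapply(
    names(ind_stat)[-1],
    function(v) !anyNA(ind_stat[[v]]) && stats::sd(ind_stat[[v]]) > 0,
    logical(1)
  )]
  indicator_res <- list(
    series = ind,
    shifts = detect_shifts(ind_stat[c("year", ind_varying)],
      alpha = stars_alpha, cutoff = stars_cutoff_fast, huber = stars_huber
    ),
    cv = cv_by_period(ind_stat[c("year", ind_varying)], cv_periods)
  )
  if (length(ind_varying) >= 2) {
    indicator_res$cc <- chronological_clustering(
      ind_stat[c("year", ind_varying)],
      alpha = cc_alpha, connectedness = cc_connectedness,
      n_perm = cc_n_perm, seed = seed + 2L
    )
  }

  out <- structure(
    list(
      forcing = forcing_res, biomass = biomass_res,
      indicators = indicator_res, trajectory = traj, networks = nets,
      config = list(
        stars = list(
          alpha = stars_alpha, cutoff_fast = stars_cutoff_fast,
          cutoff_biomass = stars_cutoff_biomass, huber = stars_huber
        ),
        cc = list(
          alpha = cc_alpha, connectedness = cc_connectedness,
          n_perm = cc_n_perm
        ),
        cv_periods = cv_periods, seed = seed,
        years = range(years)
      )
    ),
    class = "ena_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

#' @export
print.ena_pipeline <- function(x, ...) {
  cat("<ena_pipeline> years ", x$config$years[1], "-", x$config$years[2],
    "\n",
    sep = ""
  )
  cat(" forcing shifts:   ", nrow(x$forcing$shifts), "\n")
  cat(" biomass shifts:   ", nrow(x$biomass$shifts), "\n")
  cat(" indicator shifts: ", nrow(x$indicators$shifts), "\n")
  invisible(x)
}

#' Write all pipeline outputs as delimited text plus a JSON manifest
#'
#' @param pipeline An `ena_pipeline` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_pipeline <- function(pipeline, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name, units) {
    write_indicators(df, file.path(dir, name), units = units)
  }
  wt(pipeline$forcing$data, "forcing_series.tsv",
    "# forcing: F_* 1/yr, multipliers dimensionless"
  )
  wt(pipeline$forcing$shifts, "forcing_shifts.tsv", "# STARS shifts, years")
  wt(pipeline$biomass$data, "biomass_series.tsv", "# biomass t/km2")
  wt(pipeline$biomass$shifts, "biomass_shifts.tsv", "# STARS shifts, years")
  wt(pipeline$indicators$series, "indicator_series.tsv",
    "# TST/A/C/R t/km2/yr (bits-scaled for information indices); fractions dimensionless"
  )
  wt(pipeline$indicators$shifts, "indicator_shifts.tsv",
    "# STARS shifts, years"
  )
  wt(pipeline$indicators$cv, "indicator_cv.tsv",
    "# coefficient of variation (sd/|mean|), dimensionless"
  )
  if (!is.null(pipeline$forcing$traffic_light)) {
    wt(
      traffic_light_table(pipeline$forcing$traffic_light),
      "forcing_traffic_light.tsv", "# quintile bins 1 (low) .. 5 (high)"
    )
  }
  if (!is.null(pipeline$biomass$traffic_light)) {
    wt(
      traffic_light_table(pipeline$biomass$traffic_light),
      "biomass_traffic_light.tsv", "# quintile bins 1 (low) .. 5 (high)"
    )
  }
  cc_rows <- purrr::compact(list(
    forcing = pipeline$forcing$cc, biomass = pipeline$biomass$cc,
    indicators = pipeline$indicators$cc
  ))
  cc_tab <- purrr::map_dfr(names(cc_rows), function(nmx) {
    seg <- cc_rows[[nmx]]$segments
    seg$analysis <- nmx
    seg[c("analysis", "start", "end", "n")]
  })
  wt(cc_tab, "cc_segments.tsv", "# chronological clustering segments, years")

  manifest <- list(
    package = "enashift",
    version = as.character(utils::packageVersion("enashift")),
    config = pipeline$config,
    config_hash = rlang::hash(pipeline$config),
    files = list.files(dir)
  )
  jsonlite::write_json(
    manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(dir)
}
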