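#' Pipeline: simulate a synthetic cohort to disk
#'
#' Orchestration layer behind the command-line entry point
#' (`inst/cli/coxianlos.R`): each `run_*` function performs one pipeline
#' stage with plain-file inputs and outputs, logging what it wrote.
#'
#' @param config_path path to a scenario YAML/JSON (see
#'   [read_scenario]); `NULL` uses [london_scenario].
#' @param out_dir output directory.
#' @param seed overrides the scenario seed when given.
#' @return (invisibly) the [generate_cohort] result.
#' @export
run_simulate <- function(config_path = NULL, out_dir, seed = NULL) {
  config <- if (is.null(config_path)) london_scenario()
            else read_scenario(config_path)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  sim <- generate_cohort(config, dir = out_dir)
  message("wrote ", nrow(sim$records), " records across ",
          length(unique(paste(sim$records$care_type,
                              sim$records$care_group))),
          " strata to ", out_dir)
  invisible(sim)
}

#' Pipeline: fit per-stratum Coxian models from a records file
#'
#' Reads and cleans the records, builds left-truncated right-censored
#' observations per `(care_type, care_group)` stratum, selects the
#' state count per stratum by AIC/BIC up to `k_max`, and writes per
#' stratum: the fitted model JSON (`fit_<stratum>.json`), a curve table
#' (`curve_<stratum>.csv` with fitted, band and observed KM columns),
#' and a combined state-table report (`report.csv`). Strata with too
#' few discharge events to support even a one-state model are reported
#' as skipped, mirroring the exclusion of sparse strata in practice.
#'
#' @param records_path delimited records file.
#' @param window_start,window_end observation window dates.
#' @param out_dir output directory.
#' @param strata optional character vector of `"care_type/care_group"`
#'   labels to restrict to.
#' @param k_max largest state count tried.
#' @param criterion `"bic"` or `"aic"`.
#' @param bootstrap_B bootstrap replicates for the band; 0 disables.
#' @param n_starts randomized starts per fit.
#' @param seed integer seed.
#' @return (invisibly) named list of `coxian_selection` objects (or
#'   `NULL` for skipped strata).
#' @export
run_fit <- function(records_path, window_start, window_end, out_dir,
                    strata = NULL, k_max = 4, criterion = "bic",
                    bootstrap_B = 0, n_starts = 10, seed = 1L) {
  window <- observation_window(window_start, window_end)
  records <- read_stay_records(records_path)
  cleaned <- clean_stay_records(records, window)
  obs <- build_observations(cleaned, window)
  obs$stratum <- paste(obs$care_type, obs$care_group, sep = "/")
  if (!is.null(strata)) obs <- obs[obs$stratum %in% strata, , drop = FALSE]
  if (!nrow(obs)) stop("no observations in the requested strata",
                       call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  results <- list()
  report <- list()
  for (st in sort(unique(obs$stratum))) {
    sub <- obs[obs$stratum == st, , drop = FALSE]
    class(sub) <- c("stay_observations", "data.frame")
    sel <- tryCatch(
      select_coxian(sub, k_max = k_max, criterion = criterion,
                    n_starts = n_starts, seed = seed, label = st),
      error = function(e) e)
    if (inherits(sel, "error")) {
      message("stratum ", st, " skipped: ", conditionMessage(sel))
      results[[st]] <- NULL
      next
    }
    fit <- chosen_fit(sel)
    if (bootstrap_B > 0)
      fit <- bootstrap_band(fit, B = bootstrap_B, seed = seed)
    slug <- gsub("[^A-Za-z0-9]+", "_", st)
    fit_to_json(fit, file.path(out_dir, paste0("fit_", slug, ".json")))
    write_curve_table(fit, file.path(out_dir, paste0("curve_", slug,
                                                     ".csv")))
    tab <- state_table(fit$model)
    tab <- cbind(stratum = st, chosen_k = fit$model$k, tab)
    report[[st]] <- tab
    results[[st]] <- sel
    message("stratum ", st, ": chose k = ", fit$model$k, " (",
            toupper(criterion), "), loglik ", round(fit$loglik, 2))
  }
  if (!length(report))
    stop("no stratum could be fitted", call. = FALSE)
  utils::write.csv(do.call(rbind, report),
                   file.path(out_dir, "report.csv"), row.names = FALSE)
  invisible(results)
}

#' Pipeline: project occupancy of the standing cohort at an origin
#'
#' Loads a fitted model JSON and a records file, extracts the cohort in
#' care at the origin date (optionally restricted to one stratum),
#' computes expected monthly head counts from conditional survival, and
#' attaches observed counts when the records extend past the origin.
#' Writes `forecast.csv`.
#'
#' @param model_json path to a model/fit JSON written by
#'   [coxian_to_json] or [fit_to_json].
#' @param records_path delimited records file.
#' @param origin_date cohort origin date; must lie within the records'
#'   admission span.
#' @param months forecast length in months (30.4375-day steps).
#' @param out_dir output directory.
#' @param stratum optional `"care_type/care_group"` restriction.
#' @return (invisibly) the forecast data.frame.
#' @export
run_project <- function(model_json, records_path, origin_date, months,
                        out_dir, stratum = NULL) {
  obj <- jsonlite::fromJSON(model_json)
  if (!is.null(obj$model)) obj <- obj$model   # accept fit_to_json output
  model <- coxian(obj$state_means_days, obj$discharge_probs %||% numeric(0),
                  label = obj$label)
  records <- read_stay_records(records_path)
  origin_date <- as.Date(origin_date)
  span <- range(records$admission_date, na.rm = TRUE)
  last_seen <- max(c(records$discharge_date, span[2]), na.rm = TRUE)
  if (origin_date < span[1] || origin_date > last_seen)
    stop("origin date ", format(origin_date),
         " lies outside the records' span", call. = FALSE)
  if (!is.null(stratum)) {
    key <- paste(records$care_type, records$care_group, sep = "/")
    records <- records[key == stratum, , drop = FALSE]
    if (!nrow(records)) stop("no records in stratum ", stratum,
                             call. = FALSE)
  }
  cohort <- standing_population(records, origin_date)
  horizons <- monthly_horizons(months)
  fc <- expected_occupancy(model, cohort, horizons)
  if (last_seen > origin_date)
    fc <- add_observed(fc, observed_occupancy(records, origin_date,
                                              horizons))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_forecast(fc, file.path(out_dir, "forecast.csv"))
  message("projected ", attr(fc, "cohort_size"), " patients over ",
          months, " months")
  invisible(fc)
}
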