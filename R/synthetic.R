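#' Scenario configuration for the synthetic stay-record generator
#'
#' Describes a simulated continuing-care system: an observation window,
#' a burn-in period of pre-window admission history (so the window start
#' samples a standing population, exactly the mechanism that produces
#' left truncation in routine extracts), and one entry per stratum with
#' its admission rate, true Coxian length-of-stay model, and age/cost
#' marginals.
#'
#' @param window an [observation_window].
#' @param strata a list of stratum entries, each a list with
#'   `care_group`, `care_type`, `arrival_rate` (admissions/day),
#'   `model` (a [coxian]), `age` (`c(mean, sd)` years) and
#'   `weekly_cost` (`c(mean, sd)`).
#' @param burn_in days of pre-window admissions; default 10 times the
#'   largest state mean across strata, long enough for the window start
#'   to see an approximately stationary population.
#' @param seed integer seed stored with the scenario.
#' @return list of class `"scenario_config"`.
#' @export
scenario_config <- function(window, strata, burn_in = NULL, seed = 1L) {
  stopifnot(inherits(window, "observation_window"), length(strata) >= 1)
  for (s in strata) {
    stopifnot(inherits(s$model, "coxian"),
              is.numeric(s$arrival_rate), s$arrival_rate > 0,
              !is.null(s$care_group), !is.null(s$care_type))
  }
  if (is.null(burn_in))
    burn_in <- 10 * max(vapply(strata, function(s)
      max(s$model$state_means), numeric(1)))
  stopifnot(burn_in >= 0)
  structure(list(window = window, strata = strata,
                 burn_in = as.numeric(burn_in), seed = as.integer(seed)),
            class = "scenario_config")
}

#' London-calibrated scenario preset
#'
#' A two-stratum scenario using the published London-wide placement and
#' home-care three-state models, with admission rates matching the
#' published in-window totals (6189 placement and 3876 home-care
#' admissions over the 1 Apr 2005 - 31 May 2008 window, i.e. about 5.4
#' and 3.4 admissions/day) and plausible age/cost marginals.
#'
#' @param seed integer seed.
#' @param rate_scale multiplier on both admission rates (handy for
#'   smaller test runs).
#' @param burn_in override for the burn-in length (days).
#' @return a [scenario_config].
#' @export
london_scenario <- function(seed = 1L, rate_scale = 1, burn_in = NULL) {
  window <- observation_window("2005-04-01", "2008-05-31")
  span <- as.numeric(window$end - window$start)
  scenario_config(
    window,
    strata = list(
      list(care_group = "PF", care_type = "placement",
           arrival_rate = rate_scale * 6189 / span,
           model = london_placement(),
           age = c(78, 10), weekly_cost = c(650, 120)),
      list(care_group = "PF", care_type = "home_care",
           arrival_rate = rate_scale * 3876 / span,
           model = london_home_care(),
           age = c(76, 11), weekly_cost = c(420, 100))),
    burn_in = burn_in, seed = seed)
}

#' Generate a synthetic stay-record cohort
#'
#' Simulates homogeneous Poisson admissions per stratum over
#' `[window start - burn_in, window end]`, draws a complete stay
#' duration for each admission from the stratum's true Coxian model,
#' and then applies the same observability rules as a real extract:
#' stays discharged before the window start are omitted entirely
#' (inducing left truncation of the pre-window survivors), and
#' discharge dates after the window end are blanked (inducing right
#' censoring). Dates are whole days; the continuous true durations are
#' kept in the ground-truth sidecar.
#'
#' @param config a [scenario_config].
#' @param dir optional output directory; when given, writes
#'   `records.csv` (schema identical to [read_stay_records] input),
#'   `truth.json` (true parameters and per-record true durations) and
#'   `scenario.yaml`.
#' @return list of class `"synthetic_cohort"`: `records` (a
#'   `stay_records` data.frame), `truth`, `config`, and `files` when
#'   written. Strata yielding no in-window records are dropped with a
#'   warning.
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  window <- config$window
  t0 <- window$start - config$burn_in
  span <- as.numeric(window$end - t0)

  all_rec <- list()
  truth_rec <- list()
  for (si in seq_along(config$strata)) {
    s <- config$strata[[si]]
    n_arr <- stats::rpois(1, s$arrival_rate * span)
    if (n_arr == 0) {
      warning("stratum ", s$care_type, "/", s$care_group,
              " produced no admissions; omitted")
      next
    }
    arrival <- sort(stats::runif(n_arr, 0, span))
    dur_true <- simulate(s$model, nsim = n_arr)
    adm_date <- t0 + floor(arrival)
    dis_date <- adm_date + round(dur_true)
    visible <- dis_date >= window$start
    if (!any(visible)) {
      warning("stratum ", s$care_type, "/", s$care_group,
              " produced no in-window records; omitted")
      next
    }
    censored <- dis_date > window$end
    age <- s$age %||% c(75, 10)
    cost <- s$weekly_cost %||% c(500, 100)
    rec <- data.frame(
      patient_id = sprintf("S%02d-%06d", si, seq_len(n_arr)),
      care_group = s$care_group,
      care_type = s$care_type,
      admission_date = adm_date,
      discharge_date = as.Date(ifelse(censored, NA, dis_date),
                               origin = "1970-01-01"),
      discharge_reason = ifelse(censored, NA_character_,
                                sample(c("died", "home", "transfer"),
                                       n_arr, replace = TRUE,
                                       prob = c(0.6, 0.3, 0.1))),
      age_at_admission = round(pmax(18,
        stats::rnorm(n_arr, age[1], age[2]))),
      weekly_cost = round(pmax(50,
        stats::rnorm(n_arr, cost[1], cost[2])), 2),
      stringsAsFactors = FALSE)[visible, , drop = FALSE]
    all_rec[[length(all_rec) + 1L]] <- rec
    truth_rec[[length(truth_rec) + 1L]] <- data.frame(
      patient_id = rec$patient_id,
      true_duration = dur_true[visible],
      stringsAsFactors = FALSE)
  }
  if (!length(all_rec))
    stop("no stratum produced in-window records", call. = FALSE)
  records <- do.call(rbind, all_rec)
  records$invalid <- FALSE
  rownames(records) <- NULL
  class(records) <- c("stay_records", "data.frame")

  truth <- list(
    seed = config$seed,
    burn_in = config$burn_in,
    window = list(start = format(window$start), end = format(window$end)),
    strata = lapply(config$strata, function(s)
      list(care_group = s$care_group, care_type = s$care_type,
           arrival_rate = s$arrival_rate,
           state_means_days = s$model$state_means,
           discharge_probs = s$model$discharge_probs)),
    durations = do.call(rbind, truth_rec))

  out <- structure(list(records = records, truth = truth, config = config),
                   class = "synthetic_cohort")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    rec_path <- file.path(dir, "records.csv")
    write_stay_records(records, rec_path)
    truth_path <- file.path(dir, "truth.json")
    writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                                dataframe = "columns", null = "null"),
               truth_path)
    cfg_path <- file.path(dir, "scenario.yaml")
    yaml::write_yaml(.config_to_list(config), cfg_path)
    out$files <- c(records = rec_path, truth = truth_path,
                   scenario = cfg_path)
  }
  out
}

#' @keywords internal
.config_to_list <- function(config) {
  list(window = list(start = format(config$window$start),
                     end = format(config$window$end)),
       burn_in = config$burn_in,
       seed = config$seed,
       strata = lapply(config$strata, function(s)
         list(care_group = s$care_group, care_type = s$care_type,
              arrival_rate = s$arrival_rate,
              state_means_days = s$model$state_means,
              discharge_probs = s$model$discharge_probs,
              age = s$age %||% c(75, 10),
              weekly_cost = s$weekly_cost %||% c(500, 100))))
}

#' Read a scenario configuration from YAML or JSON
#'
#' @param path file written by [generate_cohort] or hand-authored with
#'   the same fields.
#' @return a [scenario_config].
#' @export
read_scenario <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  strata <- lapply(cfg$strata, function(s)
    list(care_group = s$care_group, care_type = s$care_type,
         arrival_rate = as.numeric(s$arrival_rate),
         model = coxian(as.numeric(s$state_means_days),
                        as.numeric(s$discharge_probs %||% numeric(0)),
                        label = paste(s$care_type, s$care_group, sep = "/")),
         age = as.numeric(s$age %||% c(75, 10)),
         weekly_cost = as.numeric(s$weekly_cost %||% c(500, 100))))
  scenario_config(observation_window(cfg$window$start, cfg$window$end),
                  strata, burn_in = cfg$burn_in,
                  seed = cfg$seed %||% 1L)
}

#' Standing population at a date
#'
#' Extracts the cohort of simulated (or real) patients in care on a
#' given date: admitted on or before it and not yet discharged. The
#' result carries each patient's elapsed days in care at that origin,
#' the quantity the conditional-survival projection conditions on.
#'
#' @param records a `stay_records` data.frame (e.g.
#'   `generate_cohort(config)$records`).
#' @param date origin date, inside the records' span.
#' @param window optional [observation_window]; when supplied the date
#'   must fall inside it.
#' @return data.frame of class `"care_cohort"` with columns
#'   `patient_id`, `care_type`, `care_group`, `elapsed` (days), and an
#'   `origin_date` attribute.
#' @export
standing_population <- function(records, date, window = NULL) {
  stopifnot(is.data.frame(records))
  date <- as.Date(date)
  if (!is.null(window)) {
    stopifnot(inherits(window, "observation_window"))
    if (date < window$start || date > window$end)
      stop("date ", format(date), " lies outside the observation window",
           call. = FALSE)
  }
  in_care <- records$admission_date <= date &
    (is.na(records$discharge_date) | records$discharge_date > date)
  out <- data.frame(
    patient_id = records$patient_id[in_care],
    care_type = records$care_type[in_care],
    care_group = records$care_group[in_care],
    elapsed = as.numeric(date - records$admission_date[in_care]),
    stringsAsFactors = FALSE)
  attr(out, "origin_date") <- date
  class(out) <- c("care_cohort", "data.frame")
  out
}
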