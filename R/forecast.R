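#' Monthly horizon grid
#'
#' Horizons in days for a monthly forecast: multiples of the mean
#' Gregorian month length, 365.25 / 12 = 30.4375 days.
#'
#' @param months number of months ahead.
#' @return numeric vector `c(0, 30.4375, ..., months * 30.4375)`.
#' @export
monthly_horizons <- function(months = 12) {
  stopifnot(months >= 0)
  30.4375 * (0:months)
}

#' Expected future occupancy of a standing cohort
#'
#' For each patient in care at the origin, the probability of still
#' being in care `x` days later is the conditional survival
#' `S(elapsed + x) / S(elapsed)` under the fitted length-of-stay model;
#' the expected head count at horizon `x` is the sum of these
#' probabilities over the cohort. At horizon 0 it equals the cohort
#' size exactly.
#'
#' Patients whose elapsed time already puts them numerically beyond the
#' model's support (survival underflows to zero) are excluded from the
#' sum with a warning naming them, rather than aborting the projection.
#'
#' @param model a [coxian] model (or a `coxian_fit`).
#' @param cohort a `care_cohort` from [standing_population], or a bare
#'   numeric vector of elapsed days.
#' @param horizons non-negative days-from-origin grid (default 12
#'   monthly steps).
#' @return data.frame of class `"occupancy_forecast"` with columns
#'   `horizon_days`, `expected`, `retention_fraction` and attributes
#'   `cohort_size`, `excluded`.
#' @export
expected_occupancy <- function(model, cohort,
                               horizons = monthly_horizons(12)) {
  if (inherits(model, "coxian_fit")) model <- model$model
  stopifnot(inherits(model, "coxian"))
  elapsed <- if (is.data.frame(cohort)) cohort$elapsed else as.numeric(cohort)
  if (!length(elapsed)) stop("empty cohort", call. = FALSE)
  if (any(elapsed < 0)) stop("elapsed times must be >= 0", call. = FALSE)
  stopifnot(all(horizons >= 0), !is.unsorted(horizons))

  ls_a <- coxian_survival(model, elapsed, log_p = TRUE)
  dead <- !is.finite(ls_a) | ls_a < log(.Machine$double.xmin)
  if (any(dead)) {
    warning(sum(dead), " patient(s) with elapsed time(s) ",
            paste(format(utils::head(unique(elapsed[dead]), 5)),
                  collapse = ", "),
            " days have numerically zero survival; excluded from the ",
            "projection")
    elapsed <- elapsed[!dead]
    ls_a <- ls_a[!dead]
    if (!length(elapsed)) stop("no projectable patients", call. = FALSE)
  }
  expected <- vapply(horizons, function(x)
    sum(exp(coxian_survival(model, elapsed + x, log_p = TRUE) - ls_a)),
    numeric(1))
  out <- data.frame(horizon_days = horizons, expected = expected,
                    retention_fraction = expected / length(elapsed))
  attr(out, "cohort_size") <- length(elapsed)
  attr(out, "excluded") <- sum(dead)
  class(out) <- c("occupancy_forecast", "data.frame")
  out
}

#' Observed future occupancy
#'
#' Counts, for each horizon, the patients who were in care at the
#' origin date and had not yet been discharged by origin + horizon
#' (a patient discharged exactly at a horizon is no longer counted at
#' it). The empirical counterpart of [expected_occupancy].
#'
#' @param records a `stay_records` data.frame with admission and
#'   discharge dates spanning the origin.
#' @param origin_date the origin (in-care roster date).
#' @param horizons non-negative days-from-origin grid.
#' @return integer vector of counts, one per horizon.
#' @export
observed_occupancy <- function(records, origin_date,
                               horizons = monthly_horizons(12)) {
  stopifnot(is.data.frame(records))
  origin_date <- as.Date(origin_date)
  bad <- !is.na(records$discharge_date) &
    records$discharge_date < records$admission_date
  if (any(bad))
    stop("discharge before admission in record(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  if (!nrow(records)) return(rep(0L, length(horizons)))
  in_at_origin <- records$admission_date <= origin_date &
    (is.na(records$discharge_date) | records$discharge_date > origin_date)
  rec <- records[in_at_origin, , drop = FALSE]
  days_to_discharge <- as.numeric(rec$discharge_date - origin_date)
  vapply(horizons, function(x)
    sum(is.na(days_to_discharge) | days_to_discharge > x), integer(1))
}

#' Attach observed counts to a forecast
#'
#' @param forecast an [expected_occupancy] result.
#' @param observed integer counts per horizon (e.g. from
#'   [observed_occupancy]).
#' @return the forecast with an `observed` column.
#' @export
add_observed <- function(forecast, observed) {
  stopifnot(inherits(forecast, "occupancy_forecast"),
            length(observed) == nrow(forecast))
  forecast$observed <- as.integer(observed)
  forecast
}

#' Projection summary table
#'
#' Per horizon: expected head count, retention fraction (expected
#' divided by the cohort size), and - when observed counts are present -
#' the absolute and relative deviation of the expectation from the
#' observation.
#'
#' @param forecast an [expected_occupancy] result, optionally with
#'   observed counts attached via [add_observed].
#' @return data.frame with columns `horizon_days`, `expected`,
#'   `retention_fraction` and, if available, `observed`,
#'   `abs_deviation`, `rel_deviation`.
#' @export
projection_report <- function(forecast) {
  stopifnot(inherits(forecast, "occupancy_forecast"), nrow(forecast) >= 1)
  out <- as.data.frame(forecast)
  if (!is.null(forecast$observed)) {
    out$abs_deviation <- out$expected - out$observed
    out$rel_deviation <- ifelse(out$observed > 0,
                                out$abs_deviation / out$observed, NA_real_)
  }
  out
}

#' @export
print.occupancy_forecast <- function(x, digits = 4, ...) {
  cat("Occupancy forecast for a standing cohort of",
      attr(x, "cohort_size"), "patients\n")
  if (isTRUE(attr(x, "excluded") > 0))
    cat("  (", attr(x, "excluded"), "patient(s) beyond numerical support",
        "excluded )\n")
  print(as.data.frame(x), row.names = FALSE, digits = digits)
  invisible(x)
}

#' Write a forecast as a delimited table
#'
#' Columns: `horizon_days`, `expected`, `observed` (when present),
#' `retention_fraction`.
#'
#' @param forecast an [expected_occupancy] result.
#' @param path output CSV path.
#' @export
write_forecast <- function(forecast, path) {
  tab <- projection_report(forecast)
  cols <- intersect(c("horizon_days", "expected", "observed",
                      "retention_fraction"), names(tab))
  utils::write.csv(tab[cols], path, row.names = FALSE)
  invisible(tab)
}
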