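#' Survival curve container
#'
#' A small data.frame subclass holding a survival function evaluated on
#' a time grid, with an optional pointwise confidence band.
#'
#' @param times ordered, non-negative time grid (days).
#' @param survival values in `[0, 1]`, non-increasing over `times`.
#' @param lower,upper optional band bounds containing `survival`.
#' @param source `"fitted"` or `"observed"`.
#' @return data.frame of class `"survival_curve"` with columns `times`,
#'   `survival` and, when a band is supplied, `lower`, `upper`; the
#'   `source` is stored as an attribute and column.
#' @export
survival_curve <- function(times, survival, lower = NULL, upper = NULL,
                           source = c("fitted", "observed")) {
  source <- match.arg(source)
  stopifnot(length(times) == length(survival), !is.unsorted(times),
            all(times >= 0))
  if (any(survival < -1e-9 | survival > 1 + 1e-9))
    stop("survival values must lie in [0, 1]", call. = FALSE)
  if (any(diff(survival) > 1e-9))
    stop("survival must be non-increasing", call. = FALSE)
  d <- data.frame(times = times, survival = pmin(pmax(survival, 0), 1),
                  source = source)
  if (!is.null(lower)) {
    stopifnot(length(lower) == length(times), length(upper) == length(times))
    if (any(lower > d$survival + 1e-9, na.rm = TRUE) ||
        any(upper < d$survival - 1e-9, na.rm = TRUE))
      stop("band must contain the point estimate", call. = FALSE)
    d$lower <- lower
    d$upper <- upper
  }
  attr(d, "source") <- source
  class(d) <- c("survival_curve", "data.frame")
  d
}

#' Delayed-entry Kaplan-Meier curve
#'
#' Product-limit estimate of the observed survival function with delayed
#' entry: a subject enters the risk set only after its truncation offset,
#' so the risk set at an event time `t` is
#' `{i : truncation_i < t <= duration_i}`. Computed via
#' [survival::survfit] on the counting-process form
#' `Surv(truncation, duration, event)`, which also applies the standard
#' multiplicative correction for tied events and orders events before
#' censorings tied at the same time. Greenwood pointwise confidence
#' limits are carried along.
#'
#' Risk sets can be empty early on when every subject is left-truncated
#' past the first event times; the estimate is then conditional on entry,
#' and a warning is issued.
#'
#' @param data a [stay_observations] data.frame.
#' @param grid optional time grid (days) on which to evaluate the step
#'   function (value carried forward between events; `S(0) = 1`). When
#'   `NULL` the native event-time grid (prefixed with 0) is returned.
#' @param conf_level confidence level for the Greenwood band.
#' @return a [survival_curve] with `source = "observed"`.
#' @export
km_curve <- function(data, grid = NULL, conf_level = 0.95) {
  data <- validate_stay_observations(data)
  sf <- survival::survfit(
    survival::Surv(truncation, duration, event) ~ 1,
    data = data, conf.int = conf_level, conf.type = "log")
  if (any(sf$n.risk == 0))
    warning("empty risk set at one or more event times; ",
            "step carried forward")
  times <- c(0, sf$time)
  surv <- c(1, sf$surv)
  lower <- c(1, ifelse(is.na(sf$lower), 0, sf$lower))
  upper <- c(1, ifelse(is.na(sf$upper), 1, sf$upper))
  if (!is.null(grid)) {
    stopifnot(all(grid >= 0))
    idx <- findInterval(grid, times)
    surv <- surv[idx]
    lower <- lower[idx]
    upper <- upper[idx]
    times <- grid
  }
  survival_curve(times, surv, lower = lower, upper = upper,
                 source = "observed")
}
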