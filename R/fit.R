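#' Analysis-ready stay observations
#'
#' Bundles the triples the likelihood consumes: observed duration in days
#' (admission to discharge, or to the window end if still in care), an
#' event flag (`TRUE` = discharged, `FALSE` = right-censored), and a
#' left-truncation offset (days already in care at the window start; 0
#' for admissions inside the window). The likelihood conditions each
#' contribution on survival past its truncation offset.
#'
#' @param duration positive observed durations (days).
#' @param event logical discharge indicators.
#' @param truncation non-negative truncation offsets (days), strictly
#'   less than the corresponding duration.
#' @param ... further columns (e.g. `care_type`, `care_group`) carried
#'   through unchanged.
#' @return a data.frame of class `"stay_observations"`.
#' @export
stay_observations <- function(duration, event, truncation = 0, ...) {
  d <- data.frame(duration = as.numeric(duration),
                  event = as.logical(event),
                  truncation = rep_len(as.numeric(truncation),
                                       length(duration)),
                  ...)
  validate_stay_observations(d)
}

#' @keywords internal
validate_stay_observations <- function(d) {
  stopifnot(is.data.frame(d),
            all(c("duration", "event", "truncation") %in% names(d)))
  bad <- which(!(d$duration > d$truncation & d$truncation >= 0 &
                   d$duration > 0) | is.na(d$event))
  if (length(bad))
    stop("invalid stay observation(s) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         ": need duration > truncation >= 0", call. = FALSE)
  class(d) <- unique(c("stay_observations", class(d)))
  d
}

#' Left-truncated right-censored log-likelihood
#'
#' Each discharged observation contributes `log f(t) - log S(a)`; each
#' censored observation contributes `log S(t) - log S(a)`, where `a` is
#' the truncation offset. Dividing by `S(a)` conditions on the stay
#' having already lasted `a` days, which is the only reason a
#' pre-window admission appears in the extract at all.
#'
#' @param model a [coxian] model.
#' @param data a [stay_observations] data.frame.
#' @return the log-likelihood (scalar).
#' @export
stay_loglik <- function(model, data) {
  data <- validate_stay_observations(data)
  ll <- numeric(nrow(data))
  ev <- data$event
  ll[ev] <- coxian_density(model, data$duration[ev], log_d = TRUE)
  ll[!ev] <- coxian_survival(model, data$duration[!ev], log_p = TRUE)
  tr <- data$truncation > 0
  if (any(tr))
    ll[tr] <- ll[tr] - coxian_survival(model, data$truncation[tr],
                                       log_p = TRUE)
  sum(ll)
}

# --- optimizer parametrization ---------------------------------------------
# theta = (log m1, log g2..gk, logit q1..q_{k-1}) with
# m_j = m_{j-1} * (1 + GAP_EPS + exp(g_j)): unconstrained search space that
# enforces strictly increasing state means by construction (identifiability)
# and keeps rates separated enough for the partial-fraction closed form.
.GAP_EPS <- 1e-6

#' @keywords internal
.theta_to_model <- function(theta, k, label = NULL) {
  m <- numeric(k)
  m[1] <- exp(theta[1])
  if (k > 1L)
    for (j in 2:k)
      m[j] <- m[j - 1] * (1 + .GAP_EPS + exp(theta[j]))
  q <- if (k > 1L) stats::plogis(theta[(k + 1):(2 * k - 1)]) else numeric(0)
  coxian(m, q, label = label)
}

#' @keywords internal
.model_to_theta <- function(means, q) {
  k <- length(means)
  th <- log(means[1])
  if (k > 1L)
    th <- c(th, log(pmax(means[-1] / means[-k] - 1 - .GAP_EPS, 1e-8)),
            stats::qlogis(pmin(pmax(q, 1e-6), 1 - 1e-6)))
  th
}

#' @keywords internal
.fit_start_values <- function(data, k, jitter) {
  probs <- utils::head(c(0.3, 0.7, 0.9, 0.97, 0.99), k)
  m <- as.numeric(stats::quantile(data$duration, probs = probs))
  m <- pmax(m, 0.5) * exp(stats::rnorm(k, 0, jitter))
  m <- sort(m)
  m <- m * cumprod(c(1, rep(1.01, k - 1)))      # break accidental ties
  q <- stats::plogis(stats::rnorm(max(k - 1, 0), 0, 2 * jitter))
  .model_to_theta(m, q)
}

#' Fit a Coxian length-of-stay model by maximum likelihood
#'
#' Direct quasi-Newton (BFGS) maximisation of the left-truncated,
#' right-censored log-likelihood in an unconstrained parametrization
#' (log first state mean, log multiplicative gaps between state means,
#' logit discharge probabilities), repeated from `n_starts` randomized
#' initializations (state means seeded from duration quantiles, discharge
#' probabilities near 0.5). The best local optimum is returned. For
#' `k = 1` the exponential MLE `sum(duration - truncation) / n_events`
#' is closed form and used directly.
#'
#' Fitting refuses strata with fewer than `max(10, 5 * (2k - 1))`
#' discharge events: sparse strata yield unstable latent-state estimates
#' (the motivating study likewise excluded its smallest strata).
#'
#' @param data a [stay_observations] data.frame.
#' @param k number of latent states.
#' @param n_starts number of randomized starts.
#' @param seed optional integer seed for the starts.
#' @param label stratum tag stored on the fitted model.
#' @param grid time grid (days) for the fitted survival curve; default
#'   201 points from 0 to the largest observed duration.
#' @param control passed to [stats::optim] (method `"BFGS"`).
#' @return an object of class `"coxian_fit"`: list with `model`,
#'   `loglik`, `n_params`, `aic`, `bic`, `converged`, `n_obs`,
#'   `n_events`, `curve`, `data`, `starts`.
#' @seealso [select_coxian] for choosing `k`, [bootstrap_band] for
#'   confidence bands, [km_curve] for the observed survival curve.
#' @export
fit_coxian <- function(data, k = 3, n_starts = 10, seed = NULL,
                       label = NULL, grid = NULL, control = list()) {
  data <- validate_stay_observations(data)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  n_params <- 2L * k - 1L
  n_events <- sum(data$event)
  need <- max(10L, 5L * n_params)
  if (n_events < need)
    stop("stratum too small: ", n_events, " discharge events but ",
         need, " required to fit k = ", k, " states", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  if (k == 1L) {
    m <- sum(data$duration - data$truncation) / n_events
    model <- coxian(m, label = label)
    ll <- stay_loglik(model, data)
    starts <- data.frame(start = 1L, loglik = ll, converged = TRUE)
    best <- list(model = model, loglik = ll, converged = TRUE)
  } else {
    negll <- function(theta) {
      model <- try(.theta_to_model(theta, k), silent = TRUE)
      if (inherits(model, "try-error")) return(1e10)
      v <- try(stay_loglik(model, data), silent = TRUE)
      if (inherits(v, "try-error") || !is.finite(v)) return(1e10)
      -v
    }
    ctl <- utils::modifyList(list(maxit = 500L, reltol = 1e-10), control)
    runs <- lapply(seq_len(n_starts), function(s) {
      theta0 <- .fit_start_values(data, k, jitter = if (s == 1L) 0 else 0.4)
      opt <- try(stats::optim(theta0, negll, method = "BFGS", control = ctl),
                 silent = TRUE)
      if (inherits(opt, "try-error") || !is.finite(opt$value) ||
          opt$value >= 1e10) return(NULL)
      opt
    })
    runs <- Filter(Negate(is.null), runs)
    if (!length(runs))
      stop("fit failed: no start converged for k = ", k, call. = FALSE)
    vals <- vapply(runs, `[[`, numeric(1), "value")
    opt <- runs[[which.min(vals)]]
    model <- .theta_to_model(opt$par, k, label = label)
    ll <- -opt$value
    gr <- .num_gradient(negll, opt$par)
    converged <- opt$convergence == 0L &&
      max(abs(gr)) <= 1e-6 * (1 + abs(ll))
    starts <- data.frame(start = seq_along(vals), loglik = -vals,
                         converged = vapply(runs, function(r)
                           r$convergence == 0L, logical(1)))
    best <- list(model = model, loglik = ll, converged = converged)
  }

  if (is.null(grid))
    grid <- seq(0, max(data$duration), length.out = 201)
  curve <- survival_curve(grid, coxian_survival(best$model, grid),
                          source = "fitted")
  structure(list(model = best$model, loglik = best$loglik,
                 n_params = n_params,
                 aic = 2 * n_params - 2 * best$loglik,
                 bic = n_params * log(nrow(data)) - 2 * best$loglik,
                 converged = best$converged,
                 n_obs = nrow(data), n_events = n_events,
                 curve = curve, data = data, starts = starts,
                 call = match.call()),
            class = "coxian_fit")
}

#' @keywords internal
.num_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    hi <- h * (1 + abs(x[i]))
    e <- replace(numeric(length(x)), i, hi)
    (f(x + e) - f(x - e)) / (2 * hi)
  }, numeric(1))
}

#' Select the number of latent states
#'
#' Fits Coxian models with `k = 1, ..., k_max` states and picks the one
#' minimizing AIC or BIC: the best fit with least model complexity.
#' `k_max` defaults to 4 so the data can contradict a three-state
#' assumption.
#'
#' @inheritParams fit_coxian
#' @param k_max largest state count to try.
#' @param criterion `"bic"` (default) or `"aic"`.
#' @return an object of class `"coxian_selection"`: list with `fits`
#'   (one [fit_coxian] result, or the error condition, per `k`),
#'   `chosen_k`, `criterion`, `table`.
#' @export
select_coxian <- function(data, k_max = 4, criterion = c("bic", "aic"),
                          n_starts = 10, seed = NULL, label = NULL, ...) {
  criterion <- match.arg(criterion)
  if (k_max < 1L) stop("k_max must be >= 1", call. = FALSE)
  fits <- lapply(seq_len(k_max), function(k)
    tryCatch(fit_coxian(data, k = k, n_starts = n_starts, seed = seed,
                        label = label, ...),
             error = function(e) e))
  ok <- vapply(fits, inherits, logical(1), "coxian_fit")
  if (!any(ok))
    stop("model selection failed: no state count could be fitted",
         call. = FALSE)
  crit <- vapply(fits, function(f)
    if (inherits(f, "coxian_fit")) f[[criterion]] else NA_real_, numeric(1))
  chosen <- which.min(crit)
  tab <- data.frame(k = seq_len(k_max),
                    loglik = vapply(fits, function(f)
                      if (inherits(f, "coxian_fit")) f$loglik else NA_real_,
                      numeric(1)),
                    aic = vapply(fits, function(f)
                      if (inherits(f, "coxian_fit")) f$aic else NA_real_,
                      numeric(1)),
                    bic = vapply(fits, function(f)
                      if (inherits(f, "coxian_fit")) f$bic else NA_real_,
                      numeric(1)),
                    fitted = ok)
  structure(list(fits = fits, chosen_k = chosen, criterion = criterion,
                 table = tab),
            class = "coxian_selection")
}

#' @export
print.coxian_selection <- function(x, ...) {
  cat("Coxian state-count selection by", toupper(x$criterion), "\n")
  print(x$table, row.names = FALSE)
  cat("chosen k =", x$chosen_k, "\n")
  invisible(x)
}

#' @rdname select_coxian
#' @param x a `coxian_selection` object.
#' @return `chosen_fit`: the [fit_coxian] result for the selected `k`.
#' @export
chosen_fit <- function(x) {
  stopifnot(inherits(x, "coxian_selection"))
  x$fits[[x$chosen_k]]
}

# --- coxian_fit methods -----------------------------------------------------

#' @export
print.coxian_fit <- function(x, digits = 4, ...) {
  cat("Coxian length-of-stay fit (k =", x$model$k, "states)\n")
  print(x$model, digits = digits)
  cat(sprintf("  logLik %.2f on %d parameters; AIC %.2f, BIC %.2f\n",
              x$loglik, x$n_params, x$aic, x$bic))
  cat(sprintf("  %d observations (%d events, %d censored); converged: %s\n",
              x$n_obs, x$n_events, x$n_obs - x$n_events, x$converged))
  invisible(x)
}

#' @export
summary.coxian_fit <- function(object, ...) {
  structure(list(fit = object, states = state_table(object$model),
                 mean_los = mean(object$model)),
            class = "summary.coxian_fit")
}

#' @export
print.summary.coxian_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nState table:\n")
  print(x$states, row.names = FALSE, digits = digits)
  cat(sprintf("\nMean length of stay: %.1f days (%.2f years)\n",
              x$mean_los, x$mean_los / 365.25))
  invisible(x)
}

#' @export
coef.coxian_fit <- function(object, ...) {
  m <- object$model
  stats::setNames(c(m$state_means, m$discharge_probs),
                  c(paste0("mean", seq_len(m$k)),
                    if (m$k > 1) paste0("q", seq_len(m$k - 1))))
}

#' @export
logLik.coxian_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' @export
simulate.coxian_fit <- function(object, nsim = 1, seed = NULL, ...) {
  simulate(object$model, nsim = nsim, seed = seed, ...)
}

#' Cox-Snell residuals of a Coxian fit
#'
#' The fitted cumulative hazard accrued inside the observation window,
#' `H(t) - H(a) = log S(a) - log S(t)`. Under a correct model the event
#' residuals behave like a censored unit-exponential sample.
#'
#' @param object a `coxian_fit`.
#' @param ... unused.
#' @return numeric vector, one residual per observation (attribute
#'   `event` carries the censoring flags).
#' @export
residuals.coxian_fit <- function(object, ...) {
  d <- object$data
  r <- coxian_survival(object$model, d$truncation, log_p = TRUE) -
    coxian_survival(object$model, d$duration, log_p = TRUE)
  attr(r, "event") <- d$event
  r
}

#' Predictions from a Coxian fit
#'
#' @param object a `coxian_fit`.
#' @param at times in days (`type` `"survival"`/`"density"`) or survival
#'   levels in (0,1) (`type` `"quantile"`).
#' @param type what to evaluate.
#' @param ... unused.
#' @export
predict.coxian_fit <- function(object, at,
                               type = c("survival", "density", "quantile"),
                               ...) {
  type <- match.arg(type)
  switch(type,
         survival = coxian_survival(object$model, at),
         density = coxian_density(object$model, at),
         quantile = coxian_quantile(object$model, at))
}

#' Plot fitted versus observed survival
#'
#' Draws the fitted Coxian survival curve over the delayed-entry
#' Kaplan-Meier estimate of the same observations, with the KM
#' confidence band.
#'
#' @param x a `coxian_fit`.
#' @param ... passed to [plot.default].
#' @export
plot.coxian_fit <- function(x, ...) {
  km <- km_curve(x$data, grid = x$curve$times)
  plot(km$times, km$survival, type = "s", col = "black",
       xlab = "days since admission", ylab = "P(stay > t)",
       ylim = c(0, 1), ...)
  graphics::lines(km$times, km$lower, type = "s", lty = 3)
  graphics::lines(km$times, km$upper, type = "s", lty = 3)
  graphics::lines(x$curve$times, x$curve$survival, col = "red", lwd = 2)
  graphics::legend("topright", bty = "n",
                   legend = c("observed (KM)", "fitted"),
                   col = c("black", "red"), lty = 1, lwd = c(1, 2))
  invisible(x)
}

#' Export a fit as JSON and a curve table
#'
#' `fit_to_json` writes the fitted model plus log-likelihood, AIC/BIC
#' and convergence diagnostics. `write_curve_table` writes a delimited
#' table with columns `time`, `fitted_S`, `lower`, `upper`,
#' `observed_S` (band columns only when a bootstrap band is attached).
#'
#' @param fit a `coxian_fit`.
#' @param path output file path; `fit_to_json` returns the JSON string
#'   when `path` is `NULL`.
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "coxian_fit"))
  obj <- list(model = list(label = fit$model$label, k = fit$model$k,
                           state_means_days = fit$model$state_means,
                           discharge_probs = fit$model$discharge_probs),
              loglik = fit$loglik, n_params = fit$n_params,
              aic = fit$aic, bic = fit$bic, converged = fit$converged,
              n_obs = fit$n_obs, n_events = fit$n_events)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    invisible(js)
  } else js
}

#' @rdname fit_to_json
#' @export
write_curve_table <- function(fit, path) {
  stopifnot(inherits(fit, "coxian_fit"))
  km <- km_curve(fit$data, grid = fit$curve$times)
  tab <- data.frame(time = fit$curve$times,
                    fitted_S = fit$curve$survival,
                    lower = fit$curve$lower %||% NA_real_,
                    upper = fit$curve$upper %||% NA_real_,
                    observed_S = km$survival)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
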