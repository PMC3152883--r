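#' Coxian phase-type length-of-stay model
#'
#' Constructs a Coxian phase-type distribution: a new admission passes
#' sequentially through latent exponential "stay states" (short, medium,
#' long, ...), and on leaving state *i* is either discharged (probability
#' `discharge_probs[i]`) or continues to state *i + 1*. Exit from the last
#' state is always discharge. The observable length of stay is the total
#' time until discharge.
#'
#' State means must be strictly increasing: the states are unlabelled in
#' the likelihood, and ordering them short < medium < long fixes the
#' representative (see `vignette("coxian-los")`).
#'
#' @param state_means numeric vector of `k` positive mean sojourn times,
#'   in days, strictly increasing.
#' @param discharge_probs numeric vector of `k - 1` probabilities in
#'   `[0, 1]`: the chance of discharge (rather than progressing) on
#'   leaving each of the first `k - 1` states.
#' @param label optional free-text stratum tag, e.g.
#'   `"Placement/Physically Frail"`.
#'
#' @return An object of class `"coxian"`: a list with elements `k`,
#'   `state_means`, `discharge_probs`, `label`.
#'
#' @examples
#' m <- coxian(c(25, 157, 2053), c(0.354, 0.405), label = "Placement")
#' coxian_survival(m, 148)
#' coxian_quantile(m, 0.5)
#' @export
coxian <- function(state_means, discharge_probs = numeric(0), label = NULL) {
  state_means <- as.numeric(state_means)
  discharge_probs <- as.numeric(discharge_probs)
  k <- length(state_means)
  if (k < 1L) stop("need at least one state", call. = FALSE)
  if (any(!is.finite(state_means)) || any(state_means <= 0))
    stop("state_means must be positive and finite", call. = FALSE)
  if (length(discharge_probs) != k - 1L)
    stop("discharge_probs must have length k - 1 = ", k - 1L, call. = FALSE)
  if (any(!is.finite(discharge_probs)) ||
      any(discharge_probs < 0) || any(discharge_probs > 1))
    stop("discharge_probs must lie in [0, 1]", call. = FALSE)
  if (k > 1L && any(diff(state_means) <= 0))
    stop("state_means must be strictly increasing (short < medium < long)",
         call. = FALSE)
  structure(
    list(k = k, state_means = state_means,
         discharge_probs = discharge_probs,
         label = if (is.null(label)) NULL else as.character(label)),
    class = "coxian")
}

#' @export
print.coxian <- function(x, digits = 4, ...) {
  cat("Coxian phase-type length-of-stay model",
      if (!is.null(x$label)) paste0("[", x$label, "]"), "\n")
  cat("  states:", x$k, "\n")
  cat("  state means (days):",
      paste(format(x$state_means, digits = digits), collapse = ", "), "\n")
  if (x$k > 1L)
    cat("  discharge probabilities:",
        paste(format(x$discharge_probs, digits = digits), collapse = ", "),
        "\n")
  cat("  mean length of stay:", format(mean(x), digits = digits), "days\n")
  invisible(x)
}

# Relative rate separation below which the partial-fraction closed form is
# numerically singular and the matrix-exponential path is used instead.
.RATE_SEP_TOL <- 1e-8

#' @keywords internal
.coxian_rates <- function(model) 1 / model$state_means

# Mixture decomposition of a Coxian: with probability w_j = q_j * prod(p_i, i<j)
# the stay is a hypoexponential convolution of states 1..j. For distinct rates
# this yields S(t) = sum_i c_i exp(-lambda_i t), f(t) = sum_i c_i lambda_i
# exp(-lambda_i t), with partial-fraction coefficients
# A_ij = prod_{l<=j, l!=i} lambda_l / (lambda_l - lambda_i).
#' @keywords internal
.coxian_coefs <- function(model) {
  lam <- .coxian_rates(model)
  k <- model$k
  q <- c(model$discharge_probs, 1)
  reach <- cumprod(c(1, 1 - model$discharge_probs))
  sep <- if (k > 1L) {
    # pairwise relative separation: the partial-fraction coefficients
    # blow up like 1 / ((lambda_l - lambda_i) / lambda)
    rel <- abs(outer(lam, lam, "-")) / outer(lam, lam, pmin)
    min(rel[upper.tri(rel)])
  } else Inf
  if (sep < .RATE_SEP_TOL)
    return(list(method = "expm", lambda = lam, coef = NULL))
  cvec <- numeric(k)
  for (j in seq_len(k)) {
    A <- vapply(seq_len(j), function(i) {
      l <- lam[setdiff(seq_len(j), i)]
      prod(l / (l - lam[i]))
    }, numeric(1))
    cvec[seq_len(j)] <- cvec[seq_len(j)] + q[j] * reach[j] * A
  }
  list(method = "closed", lambda = lam, coef = cvec)
}

# Sub-generator of the latent chain (absorbing discharge state omitted).
#' @keywords internal
.coxian_subgenerator <- function(model) {
  lam <- .coxian_rates(model)
  k <- model$k
  Tm <- diag(-lam, k)
  if (k > 1L)
    for (i in seq_len(k - 1L))
      Tm[i, i + 1L] <- (1 - model$discharge_probs[i]) * lam[i]
  Tm
}

# Matrix-exponential evaluation of S and f; the robust fallback when two
# rates (nearly) coincide.
#' @keywords internal
.coxian_expm_eval <- function(model, t) {
  Tm <- .coxian_subgenerator(model)
  exit <- -rowSums(Tm)                       # absorption rates q_i * lambda_i
  out <- vapply(t, function(tt) {
    occ <- as.numeric(Matrix::expm(Tm * tt)[1, ])
    c(S = sum(occ), f = sum(occ * exit))
  }, numeric(2))
  list(S = pmin(pmax(out["S", ], 0), 1), f = pmax(out["f", ], 0))
}

# log(sum_i a_i exp(-lambda_i t)) with the dominant (slowest-decaying)
# exponential factored out, so tail probabilities far beyond the longest
# state mean do not underflow.
#' @keywords internal
.log_exp_mix <- function(a, lambda, t) {
  lmin <- min(lambda)
  inner <- exp(-outer(t, lambda - lmin)) %*% a   # bounded: decaying terms
  inner <- pmax(as.vector(inner), 0)
  ifelse(inner > 0, log(inner) - lmin * t, -Inf)
}

#' Survival function of a Coxian model
#'
#' Probability `P(T > t)` that a stay lasts longer than `t` days: the total
#' probability of still occupying any latent state at time `t`. Uses the
#' distinct-rate closed form (sum of exponentials with partial-fraction
#' coefficients); when two state rates differ by less than 1e-8 relative it
#' falls back to a matrix exponential of the sub-generator.
#'
#' @param model a [coxian] model.
#' @param t non-negative time(s) in days; vectorised.
#' @param log_p return `log(S(t))` (computed stably for deep tails).
#' @return survival probabilities in `[0, 1]` (or their logs).
#' @export
coxian_survival <- function(model, t, log_p = FALSE) {
  stopifnot(inherits(model, "coxian"))
  t <- as.numeric(t)
  if (any(!is.finite(t) | t < 0)) stop("t must be >= 0", call. = FALSE)
  cf <- .coxian_coefs(model)
  if (cf$method == "expm") {
    S <- .coxian_expm_eval(model, t)$S
    return(if (log_p) log(S) else S)
  }
  ls <- .log_exp_mix(cf$coef, cf$lambda, t)
  ls <- pmin(ls, 0)
  if (log_p) ls else exp(ls)
}

#' Density of a Coxian model
#'
#' `f(t) = -dS/dt`: the instantaneous discharge rate out of all latent
#' states, weighted by their occupancy probabilities.
#'
#' @inheritParams coxian_survival
#' @param log_d return the log density.
#' @return densities per day.
#' @export
coxian_density <- function(model, t, log_d = FALSE) {
  stopifnot(inherits(model, "coxian"))
  t <- as.numeric(t)
  if (any(!is.finite(t) | t < 0)) stop("t must be >= 0", call. = FALSE)
  cf <- .coxian_coefs(model)
  if (cf$method == "expm") {
    f <- .coxian_expm_eval(model, t)$f
    return(if (log_d) log(f) else f)
  }
  ld <- .log_exp_mix(cf$coef * cf$lambda, cf$lambda, t)
  if (log_d) ld else exp(ld)
}

#' Survival quantile of a Coxian model
#'
#' Finds `t` such that `S(t) = p` by bracketed root-finding (absolute
#' tolerance 1e-6 days). Read it as an exceedance time: a fraction `p` of
#' admissions stay longer than the returned number of days.
#'
#' @inheritParams coxian_survival
#' @param p survival level(s) strictly between 0 and 1; vectorised.
#' @return time(s) in days.
#' @export
coxian_quantile <- function(model, p) {
  stopifnot(inherits(model, "coxian"))
  p <- as.numeric(p)
  if (any(!is.finite(p) | p <= 0 | p >= 1))
    stop("p must lie strictly between 0 and 1", call. = FALSE)
  vapply(p, function(pp) {
    upper <- max(model$state_means) * 2
    while (coxian_survival(model, upper) > pp) upper <- upper * 2
    stats::uniroot(function(t) coxian_survival(model, t) - pp,
                   lower = 0, upper = upper, tol = 1e-6)$root
  }, numeric(1))
}

#' Mean length of stay
#'
#' Closed-form expectation: `m1 + p1*m2 + p1*p2*m3 + ...`, each state mean
#' weighted by the probability of ever reaching that state. Equals the
#' integral of the survival function.
#'
#' @param x a [coxian] model.
#' @param ... unused.
#' @return mean stay in days.
#' @export
mean.coxian <- function(x, ...) {
  sum(reach_probabilities(x) * x$state_means)
}

#' Probability of reaching each latent state
#'
#' Element `i` is the probability that a new admission ever enters state
#' `i`: the product of continuation probabilities `1 - q_j` over earlier
#' states. Element 1 is always 1 and the sequence is non-increasing. This
#' is the "proportion of patients staying for a longer period" quantity:
#' e.g. discharge proportions 0.313 and 0.476 give a 36% long-stay reach.
#'
#' @param x a [coxian] model, or a bare numeric vector of `k - 1`
#'   discharge probabilities.
#' @return numeric vector of `k` probabilities.
#' @export
reach_probabilities <- function(x) {
  q <- if (inherits(x, "coxian")) x$discharge_probs else as.numeric(x)
  if (!inherits(x, "coxian") && (any(q < 0) || any(q > 1)))
    stop("discharge probabilities must lie in [0, 1]", call. = FALSE)
  cumprod(c(1, 1 - q))
}

#' Conditional survival
#'
#' Probability of remaining in care `horizon` more days given `elapsed`
#' days already served: `S(elapsed + horizon) / S(elapsed)`. This is the
#' per-patient building block of the occupancy projection.
#'
#' @param model a [coxian] model.
#' @param elapsed days already in care (scalar or vector, >= 0).
#' @param horizon additional days ahead (scalar or vector, >= 0).
#' @return conditional survival probabilities; recycled over the longer of
#'   `elapsed` and `horizon`.
#' @export
conditional_survival <- function(model, elapsed, horizon) {
  stopifnot(inherits(model, "coxian"))
  if (any(elapsed < 0) || any(horizon < 0))
    stop("elapsed and horizon must be >= 0", call. = FALSE)
  ls_a <- coxian_survival(model, elapsed, log_p = TRUE)
  degenerate <- !is.finite(ls_a) | ls_a < log(.Machine$double.xmin)
  if (any(degenerate)) {
    bad <- unique(elapsed[degenerate])
    stop("survival is numerically zero at elapsed time(s) ",
         paste(format(bad), collapse = ", "),
         " days; conditional survival is undefined there", call. = FALSE)
  }
  exp(coxian_survival(model, elapsed + horizon, log_p = TRUE) - ls_a)
}

#' Simulate stay durations
#'
#' Draws complete lengths of stay by sampling the latent path: an
#' exponential sojourn in each state reached, with a Bernoulli discharge
#' decision on leaving each non-terminal state.
#'
#' @param object a [coxian] model.
#' @param nsim number of durations to draw.
#' @param seed optional integer seed (uses and restores the global RNG
#'   stream like [stats::simulate]).
#' @param ... unused.
#' @return numeric vector of `nsim` positive durations (days).
#' @export
simulate.coxian <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  k <- object$k
  n <- as.integer(nsim)
  total <- stats::rexp(n, rate = 1 / object$state_means[1])
  alive <- rep(TRUE, n)
  for (i in seq_len(k - 1L)) {
    cont <- alive & (stats::runif(n) > object$discharge_probs[i])
    total[cont] <- total[cont] +
      stats::rexp(sum(cont), rate = 1 / object$state_means[i + 1L])
    alive <- cont
  }
  total
}

#' Serialize / deserialize a Coxian model as JSON
#'
#' The JSON object holds `label`, `k`, `state_means_days` and
#' `discharge_probs`, and round-trips losslessly.
#'
#' @param model a [coxian] model.
#' @param path optional file path; when given the JSON is written there.
#' @return `coxian_to_json`: JSON string (invisibly, if written to file).
#' @export
coxian_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "coxian"))
  obj <- list(label = model$label, k = model$k,
              state_means_days = model$state_means,
              discharge_probs = model$discharge_probs)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    invisible(js)
  } else js
}

#' @param x JSON string or path to a JSON file written by [coxian_to_json].
#' @return `coxian_from_json`: the reconstructed [coxian] model.
#' @rdname coxian_to_json
#' @export
coxian_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  coxian(obj$state_means_days, obj$discharge_probs %||% numeric(0),
         label = obj$label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Printed London-wide continuing-care models
#'
#' Three-state Coxian models built from published London-wide estimates:
#' placement (institutional care) with state means 25, 157 and 2053 days
#' and discharge proportions 35.4% and 40.5%; home care with state means
#' 18, 106 and 2283 days and discharge proportions 50% and 60.2%.
#'
#' @return a [coxian] model.
#' @export
london_placement <- function() {
  coxian(c(25, 157, 2053), c(0.354, 0.405), label = "Placement/London")
}

#' @rdname london_placement
#' @export
london_home_care <- function() {
  coxian(c(18, 106, 2283), c(0.50, 0.602), label = "Home care/London")
}

#' State-transition summary table
#'
#' One row per latent state: mean sojourn, discharge proportion,
#' continuation proportion, and the probability a new admission ever
#' reaches the state. This is the tabular analogue of the
#' state-and-arrow diagrams used to present fitted stay patterns.
#'
#' @param x a [coxian] model or a fitted `coxian_fit`.
#' @return a data.frame with columns `state`, `mean_days`,
#'   `discharge_prob`, `continue_prob`, `reach_prob`.
#' @export
state_table <- function(x) {
  model <- if (inherits(x, "coxian_fit")) x$model else x
  stopifnot(inherits(model, "coxian"))
  q <- c(model$discharge_probs, 1)
  labels <- if (model$k == 3L) c("short-stay", "medium-stay", "long-stay")
            else paste0("state-", seq_len(model$k))
  data.frame(state = labels,
             mean_days = model$state_means,
             discharge_prob = q,
             continue_prob = 1 - q,
             reach_prob = reach_probabilities(model))
}
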