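#' Bootstrap confidence band for a fitted survival curve
#'
#' Case-resampling bootstrap: observations are resampled with
#' replacement, the Coxian model is refitted on each replicate, and
#' pointwise percentile limits of the replicate survival curves form the
#' band. Replicates whose refit fails (or whose resample has too few
#' events) are skipped and counted; more than 20% failures aborts with
#' an error because the band would be unreliable.
#'
#' @param fit a [fit_coxian] result (its data, state count and grid are
#'   reused).
#' @param B number of bootstrap replicates (>= 100).
#' @param level band level (default 0.95).
#' @param seed integer seed; the run is reproducible given `seed`.
#' @param n_starts randomized starts per replicate refit (small by
#'   default: each replicate is warm-started from the original fit).
#' @return the `coxian_fit` with its `curve` replaced by a
#'   [survival_curve] carrying `lower`/`upper` percentile limits, and a
#'   `band` element recording `B`, `level` and the failure count.
#' @export
bootstrap_band <- function(fit, B = 500, level = 0.95, seed = NULL,
                           n_starts = 2) {
  stopifnot(inherits(fit, "coxian_fit"))
  if (B < 100) stop("B must be >= 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  data <- fit$data
  grid <- fit$curve$times
  n <- nrow(data)
  k <- fit$model$k
  warm <- fit$model

  curves <- matrix(NA_real_, nrow = B, ncol = length(grid))
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    rep_data <- data[idx, , drop = FALSE]
    refit <- tryCatch(
      .refit_warm(rep_data, k, warm, n_starts),
      error = function(e) NULL)
    if (is.null(refit)) {
      failed <- failed + 1L
    } else {
      curves[b, ] <- coxian_survival(refit, grid)
    }
  }
  if (failed > 0.2 * B)
    stop("bootstrap band unreliable: ", failed, " of ", B,
         " replicate fits failed", call. = FALSE)
  alpha <- (1 - level) / 2
  qs <- apply(curves, 2, stats::quantile,
              probs = c(alpha, 1 - alpha), na.rm = TRUE)
  lower <- pmax(pmin(qs[1, ], fit$curve$survival), 0)
  upper <- pmin(pmax(qs[2, ], fit$curve$survival), 1)
  fit$curve <- survival_curve(grid, fit$curve$survival,
                              lower = lower, upper = upper,
                              source = "fitted")
  fit$band <- list(B = B, level = level, failed = failed)
  fit
}

# Refit on a bootstrap replicate: one warm start from the original
# estimate plus (n_starts - 1) randomized starts via fit_coxian.
#' @keywords internal
.refit_warm <- function(data, k, warm, n_starts) {
  if (k == 1L) {
    if (sum(data$event) < 1) stop("no events in replicate")
    return(coxian(sum(data$duration - data$truncation) / sum(data$event)))
  }
  negll <- function(theta) {
    model <- try(.theta_to_model(theta, k), silent = TRUE)
    if (inherits(model, "try-error")) return(1e10)
    v <- try(stay_loglik(model, data), silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) return(1e10)
    -v
  }
  theta0 <- .model_to_theta(warm$state_means, warm$discharge_probs)
  opt <- stats::optim(theta0, negll, method = "BFGS",
                      control = list(maxit = 300L, reltol = 1e-9))
  best <- opt
  if (n_starts > 1L) {
    for (s in seq_len(n_starts - 1L)) {
      th <- .fit_start_values(data, k, jitter = 0.4)
      o <- try(stats::optim(th, negll, method = "BFGS",
                            control = list(maxit = 300L, reltol = 1e-9)),
               silent = TRUE)
      if (!inherits(o, "try-error") && o$value < best$value) best <- o
    }
  }
  if (!is.finite(best$value) || best$value >= 1e10)
    stop("replicate fit failed")
  .theta_to_model(best$par, k)
}
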