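# Independent oracles for the Coxian distribution and likelihood, built
# directly from the model definition (sub-generator matrix exponential and
# numerical quadrature), deliberately separate from the package's
# partial-fraction code path.

oracle_subgenerator <- function(model) {
  k <- model$k
  lam <- 1 / model$state_means
  Tm <- diag(-lam, k)
  if (k > 1)
    for (i in seq_len(k - 1))
      Tm[i, i + 1] <- (1 - model$discharge_probs[i]) * lam[i]
  Tm
}

oracle_survival <- function(model, t) {
  Tm <- oracle_subgenerator(model)
  vapply(t, function(tt) sum(as.matrix(Matrix::expm(Tm * tt))[1, ]),
         numeric(1))
}

oracle_density <- function(model, t) {
  Tm <- oracle_subgenerator(model)
  exit <- -rowSums(Tm)
  vapply(t, function(tt)
    sum(as.matrix(Matrix::expm(Tm * tt))[1, ] * exit), numeric(1))
}

oracle_loglik <- function(model, data) {
  total <- 0
  for (i in seq_len(nrow(data))) {
    li <- if (data$event[i]) log(oracle_density(model, data$duration[i]))
          else log(oracle_survival(model, data$duration[i]))
    if (data$truncation[i] > 0)
      li <- li - log(oracle_survival(model, data$truncation[i]))
    total <- total + li
  }
  total
}

# Hand-rolled delayed-entry product-limit estimator.
oracle_km <- function(duration, event, truncation, times) {
  etimes <- sort(unique(duration[event]))
  S <- 1
  step_s <- numeric(length(etimes))
  for (j in seq_along(etimes)) {
    tt <- etimes[j]
    at_risk <- sum(truncation < tt & tt <= duration)
    d <- sum(event & duration == tt)
    if (at_risk > 0) S <- S * (1 - d / at_risk)
    step_s[j] <- S
  }
  vapply(times, function(tt) {
    idx <- findInterval(tt, etimes)
    if (idx == 0) 1 else step_s[idx]
  }, numeric(1))
}

random_coxian <- function(k = 3) {
  means <- sort(exp(stats::runif(k, log(5), log(3000))))
  means <- means * cumprod(c(1, rep(1.5, k - 1)))  # enforce separation
  q <- stats::runif(max(k - 1, 0), 0.1, 0.9)
  coxian(means, q)
}

write_records_fixture <- function(lines, path = tempfile(fileext = ".csv")) {
  header <- paste("patient_id,care_group,care_type,admission_date",
                  "discharge_date,discharge_reason,age_at_admission",
                  "weekly_cost", sep = ",")
  writeLines(c(header, lines), path)
  path
}
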