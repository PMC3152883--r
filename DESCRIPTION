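Package: coxianlos
Title: Coxian Phase-Type Length-of-Stay Models and Care Occupancy Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Coxian phase-type (sequential latent short/medium/long-stay
    state) length-of-stay distributions to left-truncated, right-censored care
    episode records by direct maximum likelihood, selects the number of latent
    states by AIC or BIC, compares fitted survival against the delayed-entry
    Kaplan-Meier estimate with bootstrap confidence bands, and projects the
    expected number of current occupants remaining in care at future horizons
    from per-patient conditional survival probabilities. Includes a synthetic
    stay-record generator (Poisson admissions over an observation window with
    burn-in, inducing the same truncation and censoring mechanisms as routine
    administrative extracts) so the full pipeline is testable without
    confidential data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
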