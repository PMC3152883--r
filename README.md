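# coxianlos

Coxian phase-type length-of-stay models and occupancy forecasting for
long-term ("continuing") care systems.

Commissioners of continuing care — institutional placement and funded
home care — need two numbers to plan a budget: how long the people
currently in care will stay, and how many of them will still be in care
next month, next quarter, next year. `coxianlos` answers both from
routine administrative stay records. It fits a Coxian phase-type
distribution — admissions pass sequentially through latent
*short-stay*, *medium-stay*, *long-stay* states, with a chance of
discharge on leaving each — to durations that are **right-censored**
(stays still open at the end of the observation window) and
**left-truncated** (stays already running at its start), selects the
number of latent states by AIC/BIC, checks fit against the
delayed-entry Kaplan–Meier curve with bootstrap bands, and projects
occupancy of the standing cohort by summing per-patient conditional
survival probabilities.

## The model

With state means $m_1 < \dots < m_k$ (rates $\lambda_i = 1/m_i$) and
discharge probabilities $q_i$ on leaving state $i$
(continuation $p_i = 1-q_i$, $q_k = 1$), the stay duration has

$$S(t) = \sum_i c_i e^{-\lambda_i t},\qquad
f(t) = \sum_i c_i \lambda_i e^{-\lambda_i t},$$

with partial-fraction coefficients $c_i$ determined by the
$\lambda$'s and $q$'s. Each observation enters the likelihood as
$\log f(t) - \log S(a)$ (discharged) or $\log S(t) - \log S(a)$
(censored), where $a$ is the days already served at the window start.
The expected occupancy of a cohort with elapsed times $a_i$, $x$ days
ahead, is $\sum_i S(a_i + x)/S(a_i)$.

## Worked example

The published London-wide placement estimates (state means 25, 157,
2053 days; discharge proportions 35.4% and 40.5%) make a ready-made
model:

```r
library(coxianlos)
m <- london_placement()
coxian_quantile(m, 0.5) / 1        # 147.3  -> half stay beyond ~148 days
coxian_quantile(m, 0.2) / 365.25   # 4.19   -> 20% stay beyond ~4.2 years
state_table(m)
#>        state mean_days discharge_prob continue_prob reach_prob
#>   short-stay        25          0.354         0.646      1.000
#>  medium-stay       157          0.405         0.595      0.646
#>    long-stay      2053          1.000         0.000      0.384
```

`reach_prob` is the share of admissions that ever reach each state —
38% of placement admissions become long-stayers. Fitting recovers such
a model from data:

```r
set.seed(1)
obs <- stay_observations(simulate(m, 5000), event = TRUE)
fit <- fit_coxian(obs, k = 3, n_starts = 5, seed = 1)
summary(fit)
#> Coxian length-of-stay fit (k = 3 states)
#>   state means (days):   22.89,  162.12, 2040.26
#>   discharge probabilities: 0.3434, 0.4247
#>   logLik -35810.22 on 5 parameters; AIC 71630.44, BIC 71663.03
#>   5000 observations (5000 events, 0 censored); converged: TRUE
#> Mean length of stay: 900.0 days (2.46 years)
```

and projecting a cohort of 200 new admissions six months ahead:

```r
expected_occupancy(fit, rep(0, 200), horizons = monthly_horizons(6))
#>  horizon_days expected retention_fraction
#>           0.0    200.0              1.000
#>          30.4    145.1              0.725
#>          91.3    113.1              0.566
#>         182.6     94.5              0.473
```

i.e. about 47% of a fresh placement cohort is still in care after six
months. On real extracts the pipeline starts from a delimited records
file: `read_stay_records()` → `clean_stay_records()` (window
reconciliation, missingness rules, dual-care splitting, full exclusion
tally) → `build_observations()` → `select_coxian()` per stratum →
`standing_population()` + `expected_occupancy()`. A synthetic-records
generator (`generate_cohort()`, `london_scenario()`) produces files
with the same structure — Poisson admissions, burn-in, window
truncation and censoring — for testing without confidential data.

A thin command-line wrapper over the same functions lives at
`inst/cli/coxianlos.R` (`simulate` / `fit` / `project` subcommands).

## Scope

The package models occupancy of patients already in care; it does not
forecast new admissions, translate head counts into costs, or model
covariate effects (age, ethnicity) on survival. States are strictly
sequential and discharge is a single absorbing outcome. See
`vignettes/coxian-los.Rmd` for the methods account, numerical choices
and limitations.
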