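---
title: "Coxian length-of-stay models for continuing-care occupancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coxian length-of-stay models for continuing-care occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coxianlos)
```

## The model

Administrative length-of-stay data from long-term ("continuing") care
systems typically mix three kinds of resident: people discharged within
days, people staying a few months, and a minority staying for years.
`coxianlos` represents the observable stay duration with a Coxian
phase-type distribution: a new admission enters latent state 1
("short-stay"), resides there an exponential time with mean $m_1$, and on
leaving is discharged with probability $q_1$ or continues to state 2
("medium-stay"), and so on through $k$ strictly sequential states; exit
from the last state is always discharge. The states are *conceptual*:
they are never observed directly, only inferred from the shape of the
duration distribution.

With rates $\lambda_i = 1/m_i$ and continuation probabilities
$p_i = 1 - q_i$, the stay duration is a mixture over exit states: with
probability $w_j = q_j \prod_{i<j} p_i$ the stay is the convolution of
the first $j$ exponential sojourns (a hypoexponential distribution).
For distinct rates this gives closed forms

$$S(t) = \sum_{i=1}^{k} c_i e^{-\lambda_i t}, \qquad
  f(t) = \sum_{i=1}^{k} c_i \lambda_i e^{-\lambda_i t},$$

with partial-fraction coefficients
$c_i = \sum_{j \ge i} w_j \prod_{l \le j,\, l \ne i}
\lambda_l/(\lambda_l - \lambda_i)$. The mean stay is the
continuation-weighted sum of state means,
$E[T] = m_1 + p_1 m_2 + p_1 p_2 m_3 + \cdots$, and the probability that
an admission ever *reaches* state $i$ is $\prod_{j<i} p_j$
(`reach_probabilities()`), the quantity usually quoted as "the
proportion of long-stay patients".

## Truncation, censoring, and the likelihood

A care extract reconciled to an observation window $[w_0, w_1]$ is
informative in two asymmetric ways. A patient still in care at $w_1$
contributes survival information only (right censoring). A patient
already in care at $w_0$ is in the extract *only because* their stay
exceeded the entry delay $a = w_0 - \text{admission}$; ignoring this
left truncation would over-represent long stays. Each observation
therefore contributes

$$\ell_i = \begin{cases}
  \log f(t_i) - \log S(a_i) & \text{discharged}\\
  \log S(t_i) - \log S(a_i) & \text{censored,}
\end{cases}$$

with $a_i = 0$ for within-window admissions. `build_observations()`
derives $(t, \delta, a)$ triples from dates, and `stay_loglik()`
evaluates the sum. Log-survival is computed with the slowest-decaying
exponential factored out, so deeply truncated long-stayers do not
underflow.

## Estimation and identifiability

`fit_coxian()` maximises the likelihood directly by quasi-Newton (BFGS)
search from multiple randomized starts (state means seeded from
duration quantiles, discharge probabilities near one half). An EM-type
scheme would also work; direct maximisation was chosen because it is
easy to verify against an independently coded likelihood, and the
closed-form survival makes each evaluation cheap.

Two numerical choices matter:

* **Identifiability.** Latent states carry no labels, so any fit is
  defined only up to the representation of the distribution. The
  package fixes the representative by *constraining* the search to
  strictly increasing state means (short < medium < long): the
  parameter vector is $(\log m_1,$ log multiplicative gaps between
  successive means, logit $q_i)$, so every candidate visited is already
  in canonical order. A post-hoc sort would not do: permuting the
  (mean, discharge) pairs of a fitted Coxian changes the distribution
  except in special cases, whereas the constrained parametrization
  never leaves the canonical set.
* **Near-equal rates.** The partial-fraction closed form is singular
  when two state rates coincide. Survival and density switch to a
  matrix exponential of the latent sub-generator when any pairwise
  relative rate separation falls below $10^{-8}$; inside the optimizer
  the mean gaps are floored at a relative $10^{-6}$, which keeps every
  visited model strictly inside the closed form's comfort zone (the
  distributional effect of the floor is far below statistical
  resolution).

Convergence is declared when the optimizer reports success and the
numerical gradient satisfies
$\max_j |\partial \ell / \partial \theta_j| \le 10^{-6}(1 + |\ell|)$.
Fits are refused when a stratum has fewer than $\max(10,\ 5(2k-1))$
discharge events — sparse strata produce unstable latent-state
estimates, and dropping them mirrors how small care groups are handled
in practice. For $k = 1$ the MLE
$\hat m = \sum_i (t_i - a_i) / \#\text{events}$ is closed form and used
directly.

`select_coxian()` fits $k = 1, \dots, k_{\max}$ and minimises AIC or
BIC (default BIC, $k_{\max} = 4$: three states are the working
hypothesis for continuing care, and allowing a fourth lets the data
contradict it). The AIC/BIC identities use $2k - 1$ free parameters.

## Observed curves and uncertainty

`km_curve()` computes the delayed-entry Kaplan–Meier estimate via
`survival::survfit` on the counting-process form
`Surv(truncation, duration, event)`: a subject joins the risk set only
after its truncation offset. Tied events use the standard product-limit
multiplicative correction, and events precede censorings tied at the
same time. `bootstrap_band()` attaches a pointwise percentile band to a
fitted curve by case-resampling and refitting (default $B = 500$,
level 0.95, seeded); replicate failures are counted and more than 20%
of them aborts the band. The published curves show 95% bands without
naming their method; the percentile bootstrap is this package's choice,
made for its minimal assumptions.

## Occupancy projection

Given the standing cohort at an origin date — every patient admitted on
or before it and not yet discharged, with elapsed times $a_i$ —
the expected number still in care $x$ days later is

$$E[N(x)] = \sum_i \frac{S(a_i + x)}{S(a_i)},$$

the sum of per-patient conditional survival probabilities
(`expected_occupancy()`). `observed_occupancy()` counts the realised
head counts when the records extend past the origin, and
`projection_report()` tabulates retention fractions and deviations.
The default horizon grid is monthly at 30.4375 days (365.25/12); any
other discretisation of "monthly" changes results imperceptibly
relative to sampling noise. Patients whose elapsed time drives $S(a)$
below the smallest positive double are excluded with a warning rather
than aborting a projection run. Strata are modelled separately
throughout; pooling heterogeneous care groups into one model is
possible but blurs exactly the contrasts the latent states capture.

## The synthetic generator

The real admission extracts such models are fitted to are confidential,
so `generate_cohort()` fabricates structurally equivalent ones:
homogeneous Poisson admissions per stratum over
$[w_0 - \text{burn-in},\ w_1]$, complete stay durations drawn from the
stratum's true Coxian model, and then precisely the observability rules
of a real extract — stays ending before $w_0$ are dropped (creating
left truncation among pre-window survivors) and discharge dates after
$w_1$ are blanked (creating right censoring). The default burn-in is
ten times the largest state mean, long enough for the window start to
sample an approximately stationary population. `london_scenario()`
ships the published London-wide placement and home-care models with
admission rates matching the published in-window totals (6189 and 3876
admissions over the 38-month window).

The generator emulates the statistical structure the estimator assumes:
it does **not** reproduce seasonal or trending admission rates,
dependence of stay length on age or other attributes, movements between
placement and home care, or coding noise beyond unparseable-field
flags. Passing tests on synthetic data therefore demonstrates that the
estimation and projection machinery is correct under the model's
assumptions — not that any particular care system satisfies them; for
real data the fitted-versus-KM comparison is the check that matters.

## Worked example

```{r example, eval = FALSE}
cfg <- london_scenario(seed = 1, rate_scale = 0.2, burn_in = 3000)
sim <- generate_cohort(cfg)
obs <- build_observations(clean_stay_records(sim$records, cfg$window),
                          cfg$window)
pl <- obs[obs$care_type == "placement", ]
sel <- select_coxian(pl, k_max = 3, n_starts = 5, seed = 1)
summary(chosen_fit(sel))

cohort <- standing_population(sim$records, as.Date("2007-05-31"),
                              window = cfg$window)
expected_occupancy(chosen_fit(sel),
                   cohort[cohort$care_type == "placement", ])
```

## Test problem sizes

The package's simulation-backed tests use sizes chosen to make the
statistical assertions sharp while keeping a full test run fast:
parameter recovery on 10,000 complete draws (10% relative tolerance on
state means), state-count selection on 20,000 draws, projection
consistency on a cohort of 500 over 12 monthly horizons with binomial
99% envelopes, and bootstrap coverage over 100 exponential datasets of
$n = 200$ with $B = 199$ (where each refit is closed form). Oracle
agreement (closed form versus matrix exponential and quadrature) is
asserted to $10^{-8}$.

## Known limitations

* Strictly sequential states only: no state skipping, no re-entry, no
  admission-time mixture over entry states.
* Discharge is a single absorbing outcome; death, return home and
  transfer are not competing risks here because funding data usually
  record only that assistance ceased.
* No covariates: resident attributes (age, ethnicity) are carried
  through the records but do not enter the survival model.
* The likelihood treats durations as continuous; administrative dates
  are whole days, and zero-day stays are set to half a day. Printed
  averages of "mean length of stay" in care reports are often computed
  by undocumented rules; this package always reports the phase-type
  expectation $m_1 + p_1 m_2 + \cdots$ and states that definition.
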