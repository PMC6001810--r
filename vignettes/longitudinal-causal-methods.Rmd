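---
title: "Estimating short- and long-term treatment effects under time-dependent confounding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating short- and long-term treatment effects under time-dependent confounding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdcausal)
```

## The problem

In longitudinal observational data a time-varying covariate can be affected
by past treatment while also driving both future treatment decisions and the
outcome. Conditioning on such a covariate blocks part of the treatment
effect; ignoring it leaves confounding. This *time-dependent confounding* is
the norm in patient registries. The motivating setting for this package is
annual registry follow-up of people with cystic fibrosis: a mucolytic
maintenance treatment (binary, per year), lung function measured as percent
predicted FEV1 (continuous), and the number of days per year on intravenous
antibiotics (a count in 0–365, heavily zero-inflated). Each outcome is also a
confounder of later treatment.

`tdcausal` implements the five estimators appropriate to this structure:

1. **IPW of a marginal structural model (MSM)** — stabilized
   inverse-probability-of-treatment weights (optionally truncated at the
   1st/99th percentile, optionally multiplied by censoring weights) applied
   to a pooled regression of the outcome on lag-indexed treatment terms.
2. **History-adjusted MSM (HA-MSM)** — the weighting is re-anchored at each
   origin visit, so covariates measured before the origin can enter the
   model directly, which also permits treatment-by-covariate interactions.
3. **Sequential conditional mean models (SCMM)** — a pooled short-term
   regression of the outcome on current treatment and measured history,
   optionally augmented with the propensity score (doubly robust form).
   Only the one-year effect is identified this way.
4. **Parametric g-computation** — short-term models for every time-varying
   variable are fitted, counterfactual trajectories are simulated forward
   under each fixed treatment regime, and the regimes are contrasted with an
   unweighted final MSM.
5. **G-estimation of a structural nested mean model (SNM)** — lag-specific
   "blip" effects estimated by sequential propensity-adjusted regressions in
   which the estimated effects of later treatments are removed ("blanked")
   from the outcome.

Continuous outcomes use linear models throughout. Count outcomes use a
zero-inflated negative binomial (ZINB) likelihood — a logistic model for the
odds of a structural zero and an NB2 count model (variance
$\mu + \mu^2/\theta$, log link) — except g-estimation, which works on a
single multiplicative (rate-ratio) scale through a gamma log-link working
model. Because the count links are non-linear, marginal methods (IPW,
g-computation) and conditional methods (SCMM, HA-MSM, g-estimation) estimate
different quantities even without confounding (*non-collapsibility*); the
package deliberately reports them without forcing a common "truth" except
under a null generator, where every method must centre on zero.

## Timing conventions

Visits are `0..T` (default `T = 5`), and no one is treated at visit 0.
Within a visit the count for the past year precedes the treatment decision,
which precedes the lung-function measurement. Consequently the *one-year*
effect on lung function is `X_t -> F_t`, while the one-year effect on the
count is `X_t -> V_{t+1}`: lag-k count effects run only to `k = T - 1`, one
less than the continuous outcome. All estimators in the package share this
convention, and the MSM weight for a count outcome at visit `s` is the
stabilized weight through visit `s - 1` (times the censoring weight through
`s`).

## The synthetic cohort generator

The real registry data cannot be shipped, so the package generates synthetic
cohorts whose causal structure mirrors the registry analysis and whose
marginal distributions are calibrated to published baseline descriptives
(baseline lung function mean ≈ 86 percent, baseline IV days ≈ 7 per year,
age mean ≈ 16 years from a scaled beta distribution). Per visit the
generation order is: count given history, then treatment given (count,
previous lung function, previous treatment, age), then lung function given
(treatment, count, previous lung function, age).

Six scenarios (`make_scenario()`) vary the causal structure:

* `standard` — a one-year effect of +2 lung-function percent and a
  beneficial count effect (zero-part log-odds +0.35, rate −0.25); all
  longer-term effects arise through mediation, and every default analysis
  model is correctly specified.
* `null` — all treatment coefficients zero.
* `longterm` — adds *negative* direct effects of earlier treatment
  (lung function −0.5 at lag 2; count zero/rate −0.12/+0.10), so the total
  effect decays faster than mediation alone implies.
* `effectmod` — adds treatment-by-previous-outcome interactions
  (−0.05 lung-function percent per unit of previous lung function,
  i.e. −0.5 per 10 units, matching the magnitude reported in the registry
  analysis; count interactions +0.015 / −0.004 per previous IV day).
* `reversed` — the within-visit arrow between treatment and count is
  flipped: treatment now causes the same-year count (strongly: zero +0.9,
  rate −0.7), while every analysis still conditions the other way round.
* `censoring` — adds a missing-at-random dropout hazard increasing for
  unhealthy histories (lower lung function, more IV days), ≈ 35% censored
  by visit 5.

Design choices worth knowing:

* **Bounded confounder influence.** The treatment logit and the censoring
  hazard depend on the count through `log1p(V)`, not raw `V`. A raw count
  ranging to 365 inside a logistic model either violates positivity in the
  tail or forces negligible confounding; the log transform keeps fitted
  treatment probabilities inside (0.005, 0.995) across whole cohorts while
  leaving the confounding material. The default propensity and
  censoring-weight models use the same transform, so the standard scenario
  remains correctly specified.
* **Stable count dynamics.** The count's log-rate autoregression on the
  previous count uses coefficient 0.010. Larger values make
  `exp(c · V_prev)` explosive above moderate counts, pile probability on
  the 365-day cap and destroy the ZINB conditional law the analysis models
  assume.
* **Ground truth by common random numbers.** `true_effects()` defines the
  lag-k effect as the contrast in the final-visit outcome between "treat
  only at visit `T-k+1`" and "never treat", simulated with shared noise, so
  contrasts are exact (not Monte-Carlo) whenever mediation through the
  count is absent, and exact at lag 1 always. Under `null` the truth is
  identically zero without simulation.

What the generator does *not* emulate: additional confounders (sex,
genotype, smoking, BMI), non-annual visit spacing, separate death and
loss-to-follow-up processes, or measurement error. Passing tests on these
cohorts demonstrates internal validity of the estimators under the stated
causal structure, not performance on any real registry.

## Estimation details and numerical choices

**Weights.** Stabilized weights multiply per-visit ratios of numerator
(treatment history + visit terms only — the marginal estimand) to
denominator (full history) fitted probabilities of the treatment actually
received. Truncation clamps at pooled empirical percentiles
(linear-interpolation quantiles); the applied bounds are recorded and
re-applying the same truncation is a no-op. Fitted denominator
probabilities at the machine-precision boundary raise a positivity error.

**ZINB fitting.** Written in-package so that inverse-probability weights
enter the log-likelihood as frequency-style multipliers and cluster-robust
covariances can be assembled from the analytic per-row scores. Optimization
is a BHHH ascent (outer product of scores as curvature, halving line
search, scaled-gradient stopping rule of 1e-4 per unit weight) with a BFGS
fallback and a moment-based restart if the surface is flat at the starting
values; the observed information for the model-based covariance comes from
forward differences of the analytic gradient. Simulation studies warm-start
each fit from the previous replicate's solution. A fit with no zero counts
is flagged "no zero-inflation identifiable" rather than attempted; a
zero-part linear predictor drifting beyond ±15 sets a boundary flag.
Optimizer failures are *data*, not exceptions: the harness counts them per
method.

**HA-MSM pooling.** Reported lag-k effects come from per-lag fits that pool
all origin-outcome pairs at that lag with origin-specific intercepts,
include treatment terms for every visit from origin to outcome, and adjust
for the pre-origin covariates. Pooling *across* lags in one regression with
shared covariate coefficients was rejected: the dependence of the outcome
on pre-origin covariates genuinely varies with lag, and forcing shared
coefficients leaks that misspecification into the treatment terms. Since
origin-outcome pairs at different lags share no parameters once covariate
coefficients are lag-specific, per-lag fits are the exact equivalent of the
joint model.

**G-estimation.** The default `mode = "sequential"` estimates lag `m` from
the lag-`m` pairs only, after blanking the already-estimated effects of
intermediate treatments; each regression adjusts for pre-origin covariates
and the fitted propensity score, whose inclusion keeps the treatment
coefficient consistent under outcome-model misspecification (the propensity
residual is orthogonal to any function of the past). A `mode = "pooled"`
variant re-estimates all lags jointly from pooled pairs with shared
covariate coefficients — the textbook single-model form — but in simulation
the shared-coefficient projection breaks the orthogonality and biased all
lags (lag-1 off by ≈ 0.6 units at n = 3000 under the standard generator),
which is why it is not the default. For counts, blanking is multiplicative
(`H = V · exp(-sum of log rate effects)`), zeros are floored at 0.5 before
the gamma log-link regression (the gamma support excludes zero; the floor
is configurable in principle and documented as an assumption — the source
approach for count g-estimation leaves zero-handling unspecified), and a
single rate ratio per lag is returned: no zero-part decomposition exists on
this scale.

**G-computation.** Nuisance models are the short-term models for both
time-varying variables; the default formulas include
treatment-by-previous-outcome interaction terms so that the covariate
models remain correctly specified under the `effectmod` generator (the
interactions are truly zero elsewhere, costing only a little variance).
This matters: with interaction-free nuisance models the method inherits a
visible long-lag bias under effect modification, while its final
(population-average) MSM never contains interactions. Counterfactual
trajectories default to one Monte-Carlo replicate per person per regime
over the saturated regime set (`2^T` regimes); sampling uncertainty is
obtained by the cluster bootstrap, so the final-MSM standard errors are
reported as `NA` rather than something misleading. Two exact shortcuts keep
it fast: the continuous final MSM is fitted to regime-by-visit means
(identical to row-level weighted least squares because the design is
constant within cells), and the count ZINB is fitted to rows collapsed to
unique (regime, visit, count) cells with frequency weights (identical
likelihood).

**Standard errors.** Cluster-robust (person-level sandwich) SEs are the
default everywhere except SCMM, whose classical model-based SEs are
approximately valid when the propensity score is well estimated and are the
point of comparison for the model-vs-empirical SE check. For every
multi-step estimator the recommended uncertainty is `bootstrap_se()`:
person-level resampling with the entire pipeline (propensity models,
weights, nuisance models) refitted per resample.

## The simulation harness

`run_study()` simulates replicate cohorts, runs each requested method
specification, and reports per (method, part, lag, term): bias against the
generator truth (continuous outcomes; count outcomes only under `null`),
empirical SE, MSE, mean reported SE, the Monte-Carlo SE of the bias, and
convergence-failure counts (failures are excluded from moments but
counted). Identical `(config, methods, n_reps, n, seed)` reproduce a study
exactly.

Problem sizes: the package's test suite runs reduced-scale studies — 150
replicates at n = 1500 (standard scenario) or n = 1000 (null, effect
modification, reversed, censoring) and 500 replicates for the SCMM
standard-error calibration — with every tolerance expressed in Monte-Carlo
SEs so it scales with the chosen size. The full published design
(1000 × 7500) is a single argument change.

Interpretation caveats at reduced scale: assertions about *absence* of bias
are comparisons to ± 3 Monte-Carlo SEs and get stricter as replicates grow;
assertions about *orderings* of empirical SEs or absolute biases compare
noisy quantities, and near-ties (for example IPW versus HA-MSM at lag 5,
whose lag-5 information comes from the same origin-1 weighting) can fall
either way at a given seed.

## Effect-modification crossover arithmetic

For an additive interaction reported as an intercept (effect at modifier 0)
and a slope per 10 modifier units, `additive_crossover()` returns the
modifier value where the effect changes sign, `-10 · intercept / slope`.
For ratio-scale effects, `ratio_crossover()` returns
`-10 · log(base ratio) / log(ratio per 10)`. These reproduce the worked
registry numbers: a one-year lung-function effect of 3.32 fading by 0.57
per 10 percent crosses zero at 58 percent; 8.30 fading by 1.29 per 10
crosses at 64; an odds ratio of 0.62 for zero IV days growing by 1.16 per
10 previous IV days crosses 1 at 32 days; rate ratios of 1.12 shrinking by
0.98 and 1.36 shrinking by 0.94 cross at 56 and 50 days.

## Known limitations

* Only the saturated-lag MSM parameterization is provided (no dose-response
  or cumulative-treatment forms), matching the scope of the comparison the
  package implements.
* The ZINB dispersion is NB2 with a log link; no other count
  parameterizations are offered.
* Censoring handling is limited to MAR inverse-probability-of-censoring
  weights; death is not modelled separately.
* The g-null paradox (non-linear nuisance models jointly inconsistent with
  a sharp null) is documented rather than solved; it does not bite under
  the `null` generator here because treatment then affects neither
  time-varying variable.
* `bootstrap_se()` reruns the full pipeline per resample and is
  deliberately not used inside the simulation harness's default metrics.
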