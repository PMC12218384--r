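---
title: "Methods: within-trial cost-utility analysis with trialcua"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: within-trial cost-utility analysis with trialcua}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialcua)
```

## The estimation problem

A two-arm randomised trial collects, at baseline and two follow-up
assessments (months 0, 3, 6 by default), EQ-5D-5L health states,
healthcare resource-use counts over a 3-month recall window, 7-day
work-loss hours (WPAI absenteeism), and 7-day household food spending.
The economic question is the incremental cost per QALY of the
intervention over a 6-month horizon, under two costing perspectives:

* **NHS/PSS** — healthcare resource use priced by unit costs, pre-priced
  medication, and a one-off per-participant intervention charge
  (default £1000, 2022 GBP);
* **societal** — NHS/PSS plus productivity losses valued by the
  human-capital method and per-person food costs.

`cua()` runs the whole chain and returns a classed object; the stages are
also exported individually so any step can be run, inspected or replaced
on its own.

## Outcome construction

**Utilities.** EQ-5D-5L states are mapped to utilities by exact lookup in
a value-set table (`value_set`, `load_value_set()`). Published crosswalk
tariffs are licensed data files, so the package treats the tariff as an
input: drop in the real crosswalk CSV (columns `state`, `utility`) for
real analyses. For tests and simulation a complete synthetic additive
tariff (`synthetic_value_set()`) spans the same range, 1 for `11111` down
to −0.532 for `55555`. Partially answered questionnaires are treated as
missing utilities (there is no principled way to score an incomplete
5-tuple at the tariff level); when both responses and a pre-mapped
utility are present, responses win and a warning is raised.

**QALYs.** `auc_qaly()` is the trapezoid area under the utility-time
curve. Two scales are exposed because summary tables in this literature
are usually on the *time-weighted mean* (annualised) scale — for the
0/3/6-month schedule the weights are ¼, ½, ¼, and a constant utility u
returns u — while the literal QALY over the horizon is that mean times
the horizon in years (0.5 here). The analysis uses the time-weighted mean
scale throughout; both are available, and the choice only rescales ΔE and
λ jointly, leaving decisions unchanged. No discounting is applied: the
horizon is under a year.

**Costs.** `assemble_costs()` prices each assessment window:
counts × unit cost over the packaged 2022 unit-cost table
(`uk_unit_costs()`; GP visit £42 … outpatient appointment £165), plus
medication, plus the intervention charge at baseline for the intervention
arm. Productivity cost is hours missed × hourly wage × `period_weeks`,
with the hourly wage from an age- and sex-banded weekly wage table
divided by `standard_weekly_hours` (default 37.5 h — the conversion is a
modelling choice and is exposed because sources rarely state it). The
7-day recalls are extrapolated over `period_weeks` = 13 weeks (91/7) per
3-month window, also configurable. Food cost divides the weekly household
spend by household size before extrapolating; a missing or zero household
size is an error, never a silent divide-by-one. Participants not in
full- or part-time employment contribute a **zero** productivity cost
(absenteeism applies to workers), whereas genuinely unobserved recall
values propagate as missing for the imputation step — zeros are always
data. Cost totals cover the trial period (the two follow-up windows);
the baseline window serves as a regression adjuster. Setting
`include_baseline_in_total = TRUE` adds it to the outcome instead, for
summary tables that count the full collection period.

## Missing data

`impute_mice()` implements chained-equation multiple imputation with
Bayesian-draw predictive mean matching (type-1 matching, 5 donors,
equal-distance ties broken uniformly at random). Arms are imputed
independently — the randomised arm never predicts itself, and a
deterministic per-arm, per-imputation seed substream guarantees that one
arm's imputations are invariant to the other arm's data. Utilities are
imputed on the utility scale and costs at the level of the main cost
categories (healthcare, medication, productivity, food, per wave), with
the complete covariates (age, sex, IMD quintile, primary symptom) plus
all other wave variables as predictors. Defaults m = 10 imputations and
10 sweeps; "10 iterations" in trial reports is ambiguous between the
two, so both are set to 10 and both are configurable. PMM copies observed
donor values, so imputed utilities respect the tariff bounds and imputed
costs are nonnegative *by construction* — no post-hoc clamping, which
would distort distributions. The chain runs a fixed number of sweeps and
does not attempt convergence diagnostics; with the default fraction of
missing information (≈5% of observations) this is ample.

## Estimation and uncertainty

**SUR.** `sur_fit()` estimates the cost and effect equations jointly by
two-step feasible GLS: per-equation OLS, residual cross-equation
covariance (ML scaling, ÷n), then one GLS step. The regressor sets
deliberately differ (each equation adjusts for the baseline value of its
own outcome), which is exactly when SUR improves on OLS; with identical
regressors it reproduces OLS, an identity the tests pin at 1e-8. The
stacked normal equations are equilibrated (rescaled to unit diagonal)
before solving, because pounds² and QALY² differ by ~9 orders of
magnitude and the raw system is numerically singular; aliased columns
(e.g. a factor level absent from a bootstrap resample) are dropped from
that fit. Rank deficiency in the *full* design is an error naming the
collinear columns.

**Bootstrap within imputation.** The sequence is impute first, then
bootstrap within each completed dataset: `bootstrap_cloud()` draws B
participant resamples with replacement per imputation — stratified by
arm by default, preserving the randomised arm sizes — and refits the SUR
on each. Unstratified resampling is available; resamples that lose an
arm entirely are redrawn and counted. The m × B replicates, tagged by
imputation, form the incremental cloud used for the plane and CEAC: a
single uncertainty object that reflects both sampling and imputation
variability (clouds from different imputations are centred at different
estimates).

**Pooling.** `rubin_pool()` combines the m point estimates with
within-imputation variances taken from each imputation's bootstrap
replicates: T = W + (1 + 1/m)B per component, t-intervals with the
Barnard–Rubin small-sample degrees of freedom, and the covariance pooled
analogously (needed for INMB intervals). Percentile intervals from the
stacked cloud are reported alongside the Rubin intervals and labelled;
on well-behaved data the two agree (tested to within 15% of the interval
width), and divergence between them is itself diagnostic of skew.

## Decision outputs

`icer()` labels the plane quadrant: ratio in the NE quadrant, "dominant"
(cheaper, more effective), "dominated", an explicit flag in the SW
quadrant where the ratio's interpretation reverses, and "undefined" at
ΔE = 0. The CEAC is computed from net monetary benefit signs, not
ratios, which handles all quadrants without sign ambiguity; an NMB of
exactly zero counts as *not* cost-effective (deterministic and
conservative). CEAC(0) is the probability of being cost-saving, and the
stacked-cloud CEAC equals the replicate-weighted mean of per-imputation
CEACs (an algebraic identity, tested). Boundary points of the plane are
assigned north/east by the ≥ convention so quadrant shares always sum
to 1. Display rounding is pounds for money and 3 dp for QALYs; all CSV
and JSON exports are unrounded.

## The synthetic trial generator

`simulate_trial()` emulates the study conditions the pipeline assumes,
with every parameter exposed in `trial_params()`:

* cohort: 118 + 116 participants; 85.5% female; age ~ N(46.3, 9.85²)
  rounded and clamped to [18, 80]; IMD quintile, ethnicity, primary
  symptom and employment mixes matching a long-COVID weight-management
  cohort;
* utilities: per-wave censored normal on [−0.532, 1], latent moments
  *calibrated* so the observed mean and SD hit the targets (0.478,
  0.255) — naive truncation would shift the mean visibly. A shared
  participant intercept gives within-person correlation 0.6 across waves
  (a stated assumption; trial reports rarely publish it). The
  intervention effect (+0.08 at month 3 narrowing to +0.04 at month 6)
  is added to the censored value and re-clamped: participants at the
  ceiling cannot gain;
* healthcare costs: per-item counts from a gamma-frailty Poisson mixture
  (frailty shape 0.5), item rates allocated so expected cost matches the
  wave/arm targets — baseline means £652 (control) vs £893
  (intervention), an emulated randomisation imbalance; follow-up mean
  £885 with a −£130/wave intervention effect. The mixture yields the
  right-skewed, zero-inflated, hospitalisation-outlier-driven cost
  distributions that motivate bootstrapping. Cost noise is drawn fresh
  per wave so the structural baseline imbalance cannot bias the
  baseline-adjusted follow-up contrast;
* productivity and food: censored-normal hours (observed moments 10.5,
  14.3 among the employed; latent effect −3.5 h/week at follow-up),
  gamma household food spend (mean £70/week, −£18/week effect),
  household size 1 + Poisson(1);
* missingness: complete-then-mask. Whole follow-up assessments are
  masked with *exact* per-arm counts (defaults 1 and 36, matching the
  1/354 vs 36/348 arm imbalance), selected with probability logistic in
  baseline utility (slope −2): missing at random, dependent on arm and
  observed baseline.

`trial_truth()` returns the implied ΔE and ΔC in closed form — censored-
normal means for utilities and hours, expected per-item costs, expected
hourly wage integrated over the covariate mix, E[1/household size] for
food — so recovery and coverage experiments have an exact target. With
the default effects the exact ΔE is 0.0483; the naive ¼,½,¼ arithmetic
gives 0.05 and is reported alongside as `naive_delta_effect` (the gap is
the ceiling mass). The default productivity and food effects were chosen
once, within the uncertainty intervals such trials report, to make the
societal perspective cost-saving; `trial_params("dominant_societal")`
strengthens them and `trial_params("null")` zeroes all effects.

What the generator does **not** emulate: item-level EQ-5D response
processes (utilities are generated directly; an optional `emit_eq5d`
mode derives 5-tuples by nearest-state lookup to exercise the mapping
path), informative missingness (MNAR), dropout monotonicity, within-
person cost autocorrelation (off by default, see above), measurement
error in recall, or any long-term extrapolation beyond the trial
horizon. Passing tests therefore demonstrate correctness of the
estimation machinery under a known MAR data-generating process — not
robustness to violations real trial data may exhibit.

## Numerical choices

* Censored-normal calibration: damped fixed-point iteration on the
  closed-form censored moments, tolerance 1e-10, error if targets are
  infeasible for the bounds.
* FGLS: equilibrated normal equations (above); residual covariance gets
  a 1e-8 relative ridge only if numerically singular.
* PMM: ridge 1e-5 on the cross-product diagonal; aliased predictors
  dropped via pivoted QR; σ² drawn from the scaled inverse-χ².
* Seeds: one master seed; per-label substreams (arm × imputation,
  bootstrap × imputation) derived by integer hashing below 2³¹, so
  subsets of the computation are reproducible independently.
* Degenerate inputs are errors, not guesses: < 2 utility observations,
  missing household size, 100%-missing variables, unknown resource
  items (strict mode), currency-year mismatches.

## Validation scale

The test suite validates the chain at sizes chosen to finish in minutes
on one CPU while keeping Monte Carlo error well inside the asserted
tolerances: moment checks at n = 50,000 participants; SUR recovery at
n = 2,000; bootstrap consistency at B = 2,000; percentile-vs-Rubin
agreement at n = 500, m = 5, B = 1,000; MCAR unbiasedness over 60
replicate trials of n = 200; and full end-to-end recovery and CI
coverage over 100 replicate trials at the default n = 234 with m = 5,
B = 500.

## Known limitations

* Within-variance for Rubin's rules comes from the bootstrap replicates
  (no analytic SUR variance is assumed); with small B this adds Monte
  Carlo noise to the interval width.
* The CEAC uses the stacked m × B cloud; per-imputation CEACs are
  recoverable from the exported cloud if a different pooling device is
  preferred.
* No MNAR sensitivity analyses (delta adjustment), no friction-cost
  productivity method, no presenteeism, no acceptability frontier or
  EVPI, no multi-comparator analysis, no decision-analytic extrapolation
  beyond the trial horizon.
* The packaged wage table and value set are synthetic stand-ins of
  realistic magnitude, shipped so the pipeline is runnable and testable
  end to end; substitute licensed sources for real analyses.
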