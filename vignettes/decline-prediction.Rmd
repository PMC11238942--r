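---
title: "Modelling and predicting individualized MMSE decline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and predicting individualized MMSE decline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogtraj)
```

## The problem and the model

Amyloid-positive patients with mild cognitive impairment (MCI) or mild
dementia decline at very different rates. `cogtraj` builds prognosis models
that turn a patient's baseline profile — age, sex, baseline MMSE, APOE ε4
dose, CSF Aβ1–42 and pTau, MRI volumes — into an individualized predicted
trajectory of the MMSE (or RAVLT) over roughly five years, with explicit
uncertainty, and translates it into quantities patients ask about: the time
until a threshold score, and the time gained under a hypothetical
disease-modifying treatment.

The statistical core is a linear mixed model with a random intercept and a
random linear slope per subject around a cubic population time curve.
Writing $t' = t - 2.3$ for centered time,

$$y_{ij} = \beta_0 + \beta_1 t' + \beta_2 t'^2 + \beta_3 t'^3 +
\sum_k \gamma_k x_{ik} + \sum_k \delta_k\, x_{ik}\, t' +
b_{0i} + b_{1i} t_{ij} + \varepsilon_{ij},$$

with $(b_{0i}, b_{1i}) \sim N(0, G)$ (unstructured $2\times2$ covariance),
$\varepsilon_{ij} \sim N(0, \sigma^2)$. Baseline predictors may act as
*time-constant* effects ($\gamma_k$, shifting the whole curve) or
*time-varying* effects ($\delta_k$, tilting it). The baseline observation is
part of the response. MCI and mild dementia are always modelled separately:
diagnosis is a pipeline split, never a covariate.

Two conventions deserve emphasis because they determine every downstream
number:

* **Fixed time is centered** by subtracting 2.3 years, and the
  time-varying interactions multiply the *centered* time. At $t = 2.3$ a
  prediction therefore collapses to the intercept plus the covariate main
  effects; this identity is checked exactly in the test suite and is the
  only convention under which the shipped reference tables reproduce their
  published worked examples (with raw-time interactions the mild-dementia
  example would exceed the instrument ceiling).
* **Random effects use raw, uncentered time** — the conventional
  parameterisation of subject-level slopes. The centering applies to the
  fixed design only.

The fitted fixed effects travel as a `coef_table`: term names, estimates,
standard errors, outcome bounds and the centering constant, serialised as
JSON. Two reference tables (the published backward-selected biomarker
models for MCI and mild dementia) ship with the package and drive the
worked examples.

## Model building

**Tiers.** Candidate predictors come in three nested tiers: *base* (cubic
time, age, sex, baseline score), *biomarker* (adding APOE ε4 count, CSF
Aβ1–42, log CSF pTau, MRI total-brain and hippocampal volume), and *full*
(adding education years, depression scale, blood pressures, BMI category
and smoking history). Every covariate enters with both a main effect and a
time interaction as candidates. CSF pTau is log-transformed; its skewed
distribution makes the log scale the natural one.

**Imputation.** Baseline covariates (except age, sex, baseline score and
diagnosis, which are required complete) may be missing. `impute_chained()`
runs chained-equation multiple imputation: continuous covariates by
predictive-mean matching (Bayesian regression draw, 5 nearest observed
donors), binary covariates by logistic draws, multi-level categoricals by
multinomial draws. Donor predictors are screened per target at an absolute
pairwise-complete correlation of at least 0.05, with diagnosis always
included. Defaults are 25 imputed sets and 10 sweeps; chain-mean drift over
the last three sweeps is reported in the manifest as a programmatic
convergence check (in place of a visual inspection). Outcomes are never
imputed — only observed scores are modelled. The donor count and sweep
count are package defaults, not values the reference models are known to
have used.

**Selection.** `backward_select_one()` iteratively removes the non-forced
term with the largest Wald p-value at or above 0.10 (normal approximation;
see below). The cubic time curve and the age and sex main effects are
forced. Removal is at the granularity of single terms — a covariate's main
effect and its interaction are separately removable — because the reference
dementia model retains the pTau main effect without its interaction;
hierarchy is enforced by making a main effect unremovable while its
interaction survives. Ties on p break lexicographically by term name, so
selection is order-invariant. Across imputed sets, `stability_select()`
keeps terms selected in at least half the sets (13 of 25 qualifies, 12 does
not), repairs hierarchy, and `finalize_model()` refits the final structure
on every set and pools estimates and variances by Rubin's rules
(Barnard–Rubin degrees of freedom available when complete-data df are
supplied).

**Grouped ridge.** As an alternative to selection, `fit_grouped_ridge()`
shrinks the fixed effects with local penalties in four groups: the cubic
time curve, the baseline score, the other time-constant effects, and the
time-varying effects. Covariates are standardised internally (mean/SD) and
estimates returned on the original scale. Variance components are fixed at
their unpenalized REML estimates and the penalized generalized
least-squares problem is solved exactly, so a zero penalty reproduces the
unpenalized fit to machine precision. Penalties are tuned by inner
subject-level 5-fold cross-validated prediction error over a 20-point
log-spaced grid — first a common value, then one per-group refinement pass.
The tuning rule is a package choice; the reference analysis does not state
its own.

**Fitting and inference.** REML estimation is delegated to `lme4::lmer`
behind `fit_lmm()`; the optimizer is deterministic, so refitting reproduces
coefficients to numerical precision. Per-coefficient p-values use the
normal (z) approximation — the reference models report no degrees of
freedom, and at the cohort sizes involved the difference from a t reference
is negligible; the approximation is checked empirically (null-coefficient
p-values are uniform across simulations). Empirical-Bayes random-effect
estimates (BLUPs) are computed in closed form,
$\hat b_i = G Z_i' V_i^{-1}(y_i - X_i\hat\beta)$, and agree with the
mixed-model solver's conditional modes to $10^{-8}$.

## Evaluation

`kfold_cv()` partitions *subjects* (never observations) into 5 folds,
re-runs the chosen pipeline on each training split, and scores held-out
subjects with **fixed effects only**: a new patient's random effects are
unknowable without peeking at their outcomes, so this is the honest reading
of out-of-sample prediction. Metrics are RMSE, the median absolute
prediction error (reported as MAD), and $R^2 = 1 - SSE/SST$ with SST around
the held-out mean — negative fold values are possible and expected when a
model underperforms the mean. Baseline observations are scored by default
(the models include baseline in the response); a flag restricts scoring to
follow-up. `external_validate()` applies a frozen coefficient table to any
cohort that supplies the required covariates, without refitting.

## The prediction engine

`predict_mean()` evaluates a coefficient table for one patient;
`time_to_threshold()` locates the first crossing of a threshold on a dense
grid (0.01 y) refined by bisection to $10^{-4}$ y. Predictions are returned
unclipped with a flag when they leave the instrument range, and flagged as
extrapolation beyond five years — the models are built on roughly five
years of follow-up, and the cubic eventually turns upward outside the data
range, which is also why crossings are searched from the left.

Hypothetical treatments reducing decline by a fraction $r$ support two
mechanisms. *Time dilation* (default) evaluates the natural trajectory at a
slowed clock, $f((1-r)t)$: every crossing time scales exactly by $1/(1-r)$,
which matches both published treated worked examples (6.0→8.6 and 2.3→3.3
years, both $/0.7$) and the treated 5-year prediction. *Decline scaling*,
$f(0) - (1-r)(f(0) - f(t))$, is provided because "reduce decline by 30%"
can also be read pointwise; the two coincide for linear trajectories.
Treatment effects are assumed constant over time and disease stage — an
assumption, not a finding.

Uncertainty is communicated two ways. `simulate_individual_band()` draws
1,000 random-effect pairs and displays the interindividual spread around
one patient's mean trajectory; `percentile_of()` ranks a treated value
within that natural spread (with the default heterogeneity below, a
30%-treated median MCI patient sits near the 69th percentile of natural
5-year outcomes). `population_fan()` shows the 2nd/16th/50th/84th/98th
percentiles of predicted trajectories (fixed effects + BLUPs) across a
fitted cohort, omitting values outside the instrument bounds.

## The synthetic cohort generator

No development data are distributable, so `simulate_cohort()` generates
cohorts with the structure the analysis assumes: baseline covariates drawn
from the published group-level distributions (normal, log-normal for pTau,
categorical frequencies for sex, APOE, BMI class and smoking), trajectories
from the reference coefficient tables plus bivariate-normal random effects
and residual noise, rounded to integers and clipped to the instrument
bounds (fitting still treats the outcome as continuous, as the reference
analysis did), annual visits with small uniform jitter (±0.1 y, avoiding
exactly collinear designs) and geometric dropout.

Choices the reference analysis does not pin down, fixed once here:

* **Random-effect and residual SDs are unpublished.** Defaults are
  intercept SD 2.0 points, slope SD 1.0 points/year, correlation −0.3,
  residual SD 1.5 points. They produce a total outcome SD of ≈4 points in
  an MCI-like cohort and a random offset SD of
  $\sqrt{4 + 25 - 6} = 4.8$ points at 5 years, consistent with the
  published 90% band (≈13–30 MMSE) and the 69th-percentile treated rank.
  They are configurable and not claimed to equal the study's.
* **Dropout** is outcome-independent (MCAR) by default, with hazards 0.15/y
  (MCI) and 0.25/y (dementia) calibrated to the published mean measurement
  counts (4.2 and 3.2); an optional outcome-dependent mode increases the
  hazard for lower current scores, mimicking the observation that patients
  without follow-up scored lower at baseline. MCAR is the default so that
  parameter-recovery tests are clean.
* **Missingness** defaults mirror published availability: ≈9% for CSF,
  ≈26% for MRI volumes, small rates elsewhere; age, sex, baseline score
  and diagnosis are never masked.
* **RAVLT** has no published coefficient table; the generator uses a
  synthetic one (the MMSE table rescaled to 0–75) purely to exercise the
  pipeline on the second bounded outcome.

What passing tests on these cohorts shows — and does not show: the pipeline
recovers the generating model at realistic size and noise, selection keeps
noise near its nominal rate, and cross-validated $R^2$ on a
signal-to-noise-matched cohort lands in the published neighbourhood
(≈0.15–0.3). The generator draws covariates independently within group,
has no assay drift, scanner effects, practice effects or
informative-missingness structure, so agreement here does not certify
performance on real clinic data.

## Numerical choices and degenerate inputs

* Time-to-threshold requires the prediction at baseline to exceed the
  threshold (otherwise an explicit error) and returns `NA` flagged
  `reached = FALSE` when no crossing occurs before the horizon (20 y
  default).
* Collinear design columns are dropped by the solver; the affected
  coefficients are reported as 0 with `NA` uncertainty and are removed
  first during backward selection.
* A singular/boundary variance-component fit is accepted (zero
  heterogeneity is a legitimate limit); refusals are reserved for
  structurally broken inputs (zero outcome variance, under-10-observation
  covariates in imputation, mixed diagnosis groups).
* All randomness flows from explicit seeds; pipeline stages use fixed
  offsets of the master seed, and two runs with the same configuration are
  byte-identical.

Problem sizes in the shipped tests are chosen to exercise the statistics at
meaningful scale while keeping the suite fast: parameter recovery uses 20
cohorts of 500 subjects × 5 visits, selection operating characteristics 200
cohorts of 150 subjects, the cross-validation checks 50 pure-noise
replications plus one 310-subject cohort matching the published MCI sample
size.

## Known limitations

Wald p-values are asymptotic (no Satterthwaite/Kenward–Roger correction);
confidence intervals for time-to-threshold are not provided (they would
require the fixed-effect covariance matrix, which the reference models do
not publish); the ridge tuning rule is a faithful four-group analogue, not
a bit-level replication of the reference analysis; and predictions beyond
five years are extrapolations of a cubic fitted inside the data range and
should be treated as qualitative.
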