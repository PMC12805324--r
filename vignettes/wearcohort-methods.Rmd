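---
title: "Methods: wear-time validation, activity phenotyping and longitudinal PRO models"
author: "wearcohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wear-time validation, activity phenotyping and longitudinal PRO models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearcohort)
```

## What the package models

`wearcohort` analyses cohorts that pair minute-level consumer wearable data
(heart rate, steps, METs, device intensity codes) with patient-reported
outcomes (PROs) collected at baseline, 3 and 6 months. The pipeline has
three scientific layers:

1. **Wear-time validation.** Consumer trackers record minutes whether or not
   the device is worn, and optical heart-rate sensors produce artifacts.
   A minute is treated as valid wear when it carries a plausible observed
   heart rate; activity-gated gap filling recovers short sensor dropouts
   during movement; implausible values and flat-line runs are excluded.
2. **Behavioural phenotyping.** Valid minutes are aggregated into daily
   features (MVPA minutes, sedentary fraction, steps, heart-rate extremes,
   sleep timing), and patients are classified as MVPA-active or
   MVPA-inactive against the WHO guideline of 150 MVPA minutes/week,
   i.e. 21.4 minutes/day.
3. **Longitudinal modelling.** PRO trajectories are modelled with linear
   mixed effects (patient random intercept, group-by-time interaction,
   baseline adjustment), missingness is checked against the
   missing-completely-at-random (MCAR) hypothesis, and day-level activity
   series are explored with growth mixture models.

A seeded synthetic-cohort generator with a ground-truth ledger makes every
stage testable by parameter recovery.

## Minute-level validation rules

The validation follows heart-rate-based wear detection:

* A minute with an observed heart rate is candidate valid wear.
* A minute with *missing* heart rate is gap-filled **only** when the other
  channels show activity above the device defaults — steps > 0, METs > 1.0,
  or intensity above its default level. The fill value is the arithmetic
  mean of the nearest preceding and following observed heart rates.
* Heart rates strictly below 45 bpm or strictly above 205 bpm are excluded
  as implausible (the bounds themselves are retained).
* Runs of 11 or more consecutive identical observed heart-rate values are
  excluded as flat-line artifacts; runs of 10 or fewer are left alone.
* A **valid wear day** has at least 1200 valid minutes (20 h); a **valid
  wear patient** has at least 7 valid wear days over all available data.

Choices the rule set leaves open, and how this package resolves them:

* **Order of operations.** Gap filling runs first, then the plausibility
  window, then flat-line detection; exclusions therefore apply to filled
  values too (`exclude_filled = FALSE` restricts them to observed values).
* **"Adjacent minutes".** Neighbours for filling are the nearest
  observed-heart-rate minutes *within the same calendar day*, and a missing
  span longer than `max_fill_gap` (default 60 minutes) is never bridged —
  unbounded interpolation across hours would fabricate wear where there is
  none. Fills never seed further fills.
* **Flat-line runs** are broken by any value change and by missing minutes,
  and filled minutes do not participate: a fill is constant by
  construction and would otherwise manufacture artificial flat-lines.
* **The intensity gate.** The device default intensity is 0 (sedentary), so
  "above default" resolves to `intensity > 0`; a configuration switch
  (`intensity_gate = 1`) gives the stricter reading for sensitivity
  analysis.
* Exclusion percentages are tallied and written to the run manifest but are
  data-dependent and never asserted.

## Daily features and phenotyping

MVPA is activity above 3 METs. On the device's own scale this corresponds
to intensity codes 2–3, which the feature extractor uses directly, falling
back to `METs > 3.0` when the intensity channel is absent. Sedentary
fraction is reported relative to valid wear time, bedtimes use an
hours-past-previous-midnight scale (00:06 prints as 24.1) so averages near
midnight behave sensibly, and group summary tables average within patient
first so that patients contributing more days are not over-weighted.

Classification averages daily MVPA over *valid wear days only* — missing
days carry no information, and the pipeline deliberately performs no
imputation of whole days. "Reaching" the 21.4-minute threshold is read
inclusively (≥); the boundary behaviour is switchable and exercised by the
sensitivity machinery (`perturb_labels()`: threshold shifts, near-cutoff
swaps, minimum-day and window restrictions).

## PRO scoring

* Symptom severity is the product of frequency and intensity ratings, each
  0–4, giving the documented 0–16 composite; this is the only product form
  consistent with that range. Maximal ratings give 16.
* PHQ-2 (2 items, 0–6), GAD-7 (7 items, 0–21) and PROMIS domain raw scores
  (4 items each) are plain sums with no prorating — any missing item voids
  the total. A PHQ-2 total ≥ 3 flags likely major depressive disorder.
* PROMIS raw→T conversion requires a user-supplied lookup table: the
  conversion tables are licensed scoring-service content and are not
  shipped.
* T-score severity categories default to the conventional 1-SD/2-SD bands:
  60/70 for higher-worse domains, mirrored at 40/30 for lower-worse domains
  (physical function, social roles, cognition). The cutoffs are
  configurable because no single standard is universal.
* Change scores are strictly pairwise within subject; a patient missing
  either wave contributes nothing to that cell, so cell sample sizes shrink
  with dropout. Follow-up symptom items exist only for symptoms reported at
  baseline, and the generator honours the same gating.

## Group comparisons and the MCAR test

`compare_groups()` picks its test from the data type and normality:
chi-squared (no continuity correction by default) for categorical data, and
for continuous data Shapiro-Wilk at α = .05 per group decides between the
pooled-variance Student t and the Wilcoxon rank-sum test (exact p below
n = 25 with no ties, normal approximation otherwise). Two-way ANOVA uses
Type II sums of squares via `car::Anova`, matching its role of checking
that group differences survive adjustment for a second factor.

The missingness check groups cases by missingness pattern and asks whether
the patterns behave like random subsamples of one multivariate normal
population, i.e. have equal means and equal covariances:

* the **mean** component is a likelihood-ratio comparison of pattern-wise
  observed means against EM-estimated normal parameters;
* the **covariance/normality** component is the Hawkins k-sample statistic:
  within-pattern studentized distances are mapped to F tail areas
  (`B = n_i d_ij/(n_i - 1)` is Beta-distributed under the null) and each
  pattern's tail areas are tested for uniformity with a four-component
  Neyman smooth statistic, computed after one stochastic
  conditional-normal imputation;
* the overall p-value Fisher-combines the two components.

Patterns with fewer than 6 cases are dropped (the within-pattern dispersion
is otherwise too unstable), complete data or a single pattern leave the
test undefined, and the imputation draws from the seeded RNG stream. The
test suite verifies by simulation that the null rejection rate sits at the
nominal α and that strongly value-driven (MNAR) missingness is detected
with high power.

## Longitudinal mixed-effects models

The default model regresses the outcome at all three waves on time (coded
0/1/2 in 3-month units, so the interaction reads "per 3 months"), phenotype
group (inactive is the reference level), their interaction, and the
baseline score, with a patient random intercept, fitted by REML. P-values
use Satterthwaite degrees of freedom and intervals are Wald — the dominant
convention for this toolchain; profile intervals are not provided.

Modelling baseline rows as outcomes *while* the baseline score is a
covariate is unusual (the baseline outcome and the covariate coincide), so
both variants ship: the literal model is the default and the
follow-up-rows-only model is a named entry in the sensitivity grid. A
simulation study in the test suite shows the default is well calibrated
under the cohort's conditions — interaction recovery is unbiased to within
±0.15 T and 95% interval coverage is ≈ 0.93–0.94 — with a mild
anti-conservatism of the interaction test (empirical size ≈ 0.065 at
nominal .05) that traces to the duplicated baseline information; the
follow-up-only variant behaves almost identically here.

AIC-based model selection refits candidates by maximum likelihood (REML
AICs are not comparable across fixed-effect structures) and refuses
candidates fitted to different observation sets. Diagnostics report
Shapiro-Wilk on conditional residuals and the White Lagrange-multiplier
test (squared residuals regressed on fitted values and their squares,
n·R² against χ²₂); nothing is refitted automatically. Interaction
estimates of T-score outcomes at or beyond 3 T points are annotated as
reaching the conventional meaningful-change threshold. Degenerate inputs
(constant outcome) return a flagged zero-slope fit rather than an error.

## Growth mixture model

The growth mixture model is a finite mixture of linear day-level
trajectories: class-specific fixed intercept and slope over days since each
patient's deployment, with a patient random-intercept variance and residual
variance shared across classes. This is the simplest mixture consistent
with reporting per-class intercepts and slopes; richer covariance
structures are deliberately out of scope. The marginal likelihood per
patient uses the closed-form inverse of the compound-symmetric covariance,
so EM iterations run on six sufficient statistics per patient.

Numerical choices: the first restart initialises from a deterministic
quantile split of patient means and later restarts randomise (all seeded);
the observed log-likelihood is asserted non-decreasing at every iteration;
a class whose mixing proportion falls below 1/n triggers a restart; classes
are canonicalised in ascending intercept order so labels are reproducible;
BIC uses the number of patients as the sample size (the independent units);
ties in class-count selection go to the smaller K. Standard errors come
from the numerical Hessian of the full-parameter log-likelihood. At K = 1
the model coincides with a random-intercept linear model, which the test
suite verifies against `lme4` to 4 decimals in log-likelihood. Mixture
results are exploratory and feed nothing downstream.

## The synthetic cohort generator

The generator encodes the study conditions as defaults: 41 MVPA-active and
41 MVPA-inactive patients; per-patient valid-day counts lognormal with
`meanlog = log(42)` and `sdlog = 0.936` — matching the observed median of
42 days and the observed quartile ratio (a two-parameter lognormal cannot
match both quartiles of an asymmetric IQR exactly) — clamped to ≥ 7 days;
group daily-MVPA means 46.9/8.2 with between-patient SDs 31.4/6.3 and a
within-patient day-to-day SD of 12 minutes (chosen as a realistic
day-level dispersion; day values truncate at zero); steps, resting heart
rate, sleep timing and efficiency at the observed group means; PRO
baseline group means per measure with a patient-intercept SD of 8 and
residual SD of 6 (yielding cross-sectional SDs near 10 and change-score
SDs near 10, as observed); wave dropout MCAR at 0/30%/30%; and a
social-roles T-score slope of 0 (active) vs +4.21 per 3 months (inactive),
i.e. an active-vs-inactive interaction of −4.21 with the inactive group
improving.

Minute-level streams are built from a circadian heart-rate baseline
(sinusoid plus AR(1) noise around the patient's resting level, reflected —
not clamped — at the 46/204 bounds so no artificial flat-lines pile up at
the boundary), a sleep window with low heart rate and zero steps, and
activity bouts that raise intensity, METs, steps and heart rate jointly;
intensity ≥ 2 always implies METs > 3 and positive steps. Artifacts are
then injected and registered in a ledger: rest-time heart-rate deletions
(which fail the activity gate and become nonwear), short activity-time
deletions (fillable), flat-line runs drawn from 8–15 minutes so they
straddle the 11-minute rule, and spikes outside the plausibility window at
roughly the observed exclusion rates. Because clean-stream heart rate stays
inside 46–204 and artifacts are placed without overlap, pipeline exclusion
counts equal ledger injection counts exactly, which the tests assert.

What the generator does **not** emulate: posture, heart-rate variability,
sleep stages, weekly routines, autocorrelated missingness, or informative
(wear-related) PRO dropout. Passing recovery tests therefore demonstrates
that the pipeline measures what the generator encodes — not that real
sensor data are this well behaved.

## Problem sizes used by the shipped simulations

The test suite's simulation studies use: 50 random 10,000-minute streams
for the filter-oracle equivalence; 200 replicates of the 82-patient cohort
for interaction recovery and interval coverage; 500 replicates for the size
of the interaction test; 50 replicates of the 82-patient, 50-day cohort for
mixture recovery and class-count selection; and 200 null plus 60
alternative replicates at n = 200 for the missingness test. These sizes
give Monte-Carlo standard errors comfortably inside the asserted bands.
The end-to-end pipeline demonstration runs a 3-patient, 8-day miniature so
that the determinism check exercises every stage quickly.

## Known limitations

* The wear-validation rules are heart-rate based; accelerometer nonwear
  algorithms (Choi, Troiano) are out of scope.
* PROMIS T-score conversion depends on a user-supplied table.
* The mixture model fits linear trajectories with shared variances only.
* Whole missing days are never imputed, by design.
* The Hawkins-style MCAR test assumes approximate multivariate normality;
  heavy-tailed complete data can inflate its covariance/normality
  component.
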