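# wearcohort

Analysis pipeline for cohort studies that pair **minute-level consumer
wearable data** (heart rate, steps, METs, intensity) with **repeated
patient-reported outcomes** (PROs), as used in long COVID / ME/CFS
monitoring: wear-time validation, daily behavioural features, MVPA
phenotyping, PRO scoring, missingness testing, longitudinal mixed-effects
models and growth mixture models — plus a seeded synthetic-cohort
generator with a ground-truth ledger so every stage is testable by
parameter recovery.

## Who it is for

Biostatisticians and digital-health researchers who receive Fitabase-style
minute CSV exports and questionnaire tables and need a reproducible,
tested path from raw minutes to longitudinal effect estimates.

## The core methods

**Wear validation.** A minute is valid wear when it carries a plausible
observed heart rate. Missing-HR minutes are gap-filled with the mean of the
nearest observed neighbours *only* when activity channels exceed device
defaults (steps > 0, METs > 1.0, intensity > 0). HR < 45 or > 205 bpm is
excluded; so is every minute of a run of ≥ 11 identical consecutive HR
values. A valid day has ≥ 1200 valid minutes; a valid-wear patient has
≥ 7 valid days.

**Phenotyping.** Patients are MVPA-active when average daily MVPA over
valid days reaches 150/7 ≈ 21.4 minutes (the WHO weekly guideline divided
across the week); MVPA is activity above 3 METs (device intensity 2–3).

**Longitudinal model.** For an outcome y of patient *i* at wave
*t* ∈ {0, 1, 2} (3-month units):

    y_it = β0 + β1 t + β2 active_i + β3 (t × active_i) + β4 y_i0 + u_i + e_it,
    u_i ~ N(0, σ_u²),  e_it ~ N(0, σ_e²)

fitted by REML with Satterthwaite df; β3 is the group-by-time interaction
("per 3 months of being MVPA-active"). Growth mixture models fit latent
classes of linear day-level trajectories by EM with a shared patient
random intercept; the MCAR check compares missingness-pattern groups for
equal means (Little-type LRT) and equal covariances/normality (Hawkins
k-sample statistic), Fisher-combined.

## Worked example

```r
library(wearcohort)

# a small synthetic cohort written as the CSV dialects the readers consume
cfg   <- cohort_config(n_active = 3, n_inactive = 3, fixed_days = 10, seed = 7)
paths <- make_fixture_suite(file.path(tempdir(), "demo"), cfg)

minutes <- read_minute_csv(paths["minutes"])
val     <- validate_cohort(minutes)
val$exclusion_tally[c("valid_observed", "valid_filled", "flatline_run", "nonwear")]
#> $valid_observed  83150
#> $valid_filled      253
#> $flatline_run      903
#> $nonwear          1905

days   <- summarize_days(val, read_sleep_csv(paths["sleep"]))
labels <- classify_cohort(days)
labels[, c("patient_id", "mean_daily_mvpa", "label", "n_valid_days")]
#>   patient_id mean_daily_mvpa    label n_valid_days
#> 1       P001           123.9   active           10
#> 2       P002            12.5 inactive           10
#> ...
```

Of 86,400 generated minutes, 83,150 carried valid observed heart rate, 253
were recovered by activity-gated gap filling, 903 fell in injected
flat-line runs and 1905 were nonwear — the tallies the validator logs for
every run. Patient P001 averages 123.9 MVPA min/day (≥ 21.4 ⇒ active).

Fitting the longitudinal model on a full-size synthetic cohort (82
patients, 30% wave dropout) whose generator encodes a social-roles
T-score interaction of −4.21 per 3 months:

```r
patients <- data.frame(patient_id = sprintf("P%03d", 1:82),
                       group = rep(c("active", "inactive"), each = 41))
waves <- generate_pro_waves(patients, cohort_config(seed = 7))
d <- waves$pro[waves$pro$measure == "social_roles_t", ]
d$group <- patients$group[match(d$patient_id, patients$patient_id)]
fit <- fit_lme(d, lme_spec("social_roles_t"))
fit$interaction
#>               term estimate        se  df           p     ci_lo     ci_hi
#> 5 time:groupactive -4.82516 0.9516857 201 9.00105e-07 -6.701728 -2.948591
```

The interaction estimate −4.83 (95% CI −6.70 to −2.95) recovers the
generated −4.21 within its interval: relative to the inactive group, the
active group's social-roles T-score declines about 4.8 points per 3
months in this draw. `diagnose_fit(fit)` adds Shapiro-Wilk and White
Lagrange-multiplier residual checks, `sensitivity_grid()` refits the model
under alternative labelings, time codings and inclusion rules, and
`fit_gmm()` / `select_classes()` explore latent day-level activity
classes.

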