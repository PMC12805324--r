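Package: wearcohort
Title: Wearable Wear-Time Validation and Longitudinal Patient-Reported
    Outcome Modelling for Long COVID Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline for cohort studies that pair minute-level
    consumer wearable data (heart rate, steps, METs, intensity) with repeated
    patient-reported outcomes. Implements heart-rate-based wear-time
    validation (activity-gated gap filling, plausibility and flat-line
    exclusion, valid-day and valid-patient rules), daily behavioural feature
    extraction, MVPA-based activity phenotyping against the WHO guideline,
    CDC-style symptom severity and PROMIS/PHQ-2/GAD-7 scoring,
    missing-completely-at-random testing of outcome missingness,
    baseline-adjusted linear mixed-effects trajectory models with a
    group-by-time interaction and a sensitivity-analysis grid, and growth
    mixture modelling of day-level activity series. A seeded synthetic cohort
    generator with a ground-truth ledger supports parameter-recovery testing
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
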