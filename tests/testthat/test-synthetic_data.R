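small_cfg <- function(seed, ...) {
  cohort_config(n_active = 1, n_inactive = 1, fixed_days = 2, seed = seed, ...)
}

test_that("generation is deterministic under a fixed seed", {
  g1 <- generate_cohort_minutes(small_cfg(101))
  g2 <- generate_cohort_minutes(small_cfg(101))
  expect_identical(g1$minutes, g2$minutes)
  expect_identical(g1$truth$artifacts, g2$truth$artifacts)
  g3 <- generate_cohort_minutes(small_cfg(102))
  expect_false(identical(g1$minutes$hr, g3$minutes$hr))
})

test_that("clean streams validate to 1440 valid minutes per day", {
  cfg <- small_cfg(103)
  gen <- generate_cohort_minutes(cfg, inject_artifacts = FALSE)
  val <- validate_cohort(gen$minutes)
  expect_true(all(val$days$valid_minutes == 1440))
  expect_equal(sum(val$minutes$status == "excluded"), 0)
  expect_equal(sum(val$minutes$status == "nonwear"), 0)
})

test_that("generated signals never contradict each other", {
  gen <- generate_cohort_minutes(small_cfg(104))
  m <- gen$minutes
  mvpa <- !is.na(m$intensity) & m$intensity >= 2
  expect_true(all(m$mets[mvpa] > 3))
  expect_true(all(m$steps[mvpa] > 0))
  sed <- !is.na(m$intensity) & m$intensity == 0
  expect_true(all(m$steps[sed] == 0))
  expect_true(all(m$mets[sed] <= 1))
})

test_that("ledger artifacts match pipeline exclusions exactly", {
  cfg <- cohort_config(n_active = 2, n_inactive = 2, fixed_days = 4,
                       seed = 105, flatline_runs_per_day = 2,
                       flatline_len_range = c(15, 15),
                       hr_missing_act_runs = 0)
  gen <- generate_cohort_minutes(cfg)
  val <- validate_cohort(gen$minutes)
  art <- gen$truth$artifacts
  fl <- art[art$type == "flatline", ]
  # every injected run of >= 11 minutes is flagged minute-for-minute
  expect_equal(sum(val$minutes$reason == "flatline_run"),
               sum(fl$length[fl$length >= 11]))
  expect_equal(sum(val$minutes$reason == "hr_below_min"),
               sum(art$type == "spike_low"))
  expect_equal(sum(val$minutes$reason == "hr_above_max"),
               sum(art$type == "spike_high"))
})

test_that("runs straddling the 11-minute rule split as expected", {
  cfg <- cohort_config(n_active = 3, n_inactive = 0, fixed_days = 5,
                       seed = 106, flatline_runs_per_day = 3,
                       flatline_len_range = c(8, 15),
                       spike_low_rate = 0, spike_high_rate = 0)
  gen <- generate_cohort_minutes(cfg)
  art <- gen$truth$artifacts
  fl <- art[art$type == "flatline", ]
  expect_true(any(fl$length <= 10) && any(fl$length >= 11))
  val <- validate_cohort(gen$minutes)
  expect_equal(sum(val$minutes$reason == "flatline_run"),
               sum(fl$length[fl$length >= 11]))
})

test_that("pipeline MVPA tracks the generator's per-patient target", {
  cfg <- cohort_config(n_active = 1, n_inactive = 0, fixed_days = 20,
                       seed = 107,
                       mvpa_sd_between = c(active = 0, inactive = 0))
  gen <- generate_cohort_minutes(cfg, inject_artifacts = FALSE)
  val <- validate_cohort(gen$minutes)
  ds <- summarize_days(val)
  expect_lt(abs(mean(ds$mvpa_minutes) - 46.9), 5)
  # ledger day-level truth matches the observed minute counts
  expect_equal(ds$mvpa_minutes, gen$truth$day_mvpa$true_mvpa)
})

test_that("PRO waves: zero effect and zero noise replicate the baseline", {
  pts <- mk_patients(4, 4)
  cfg <- cohort_config(
    pro_measures = list(fatigue_t = list(mean = c(active = 59, inactive = 66),
                                         slope = c(active = 0, inactive = 0),
                                         range = c(20, 80), integer = FALSE)),
    symptoms = list(), patient_sd = 0, resid_sd = 0,
    dropout = c(baseline = 0, m3 = 0, m6 = 0), seed = 108)
  pw <- generate_pro_waves(pts, cfg)
  d <- pw$pro[pw$pro$measure == "fatigue_t", ]
  by_wave <- split(d$value, d$wave)
  expect_equal(by_wave$baseline, by_wave$m3)
  expect_equal(by_wave$baseline, by_wave$m6)
  # zero dropout -> complete three-wave records for everyone
  expect_equal(nrow(d), 3 * nrow(pts))
})

test_that("symptom follow-up is gated on baseline presence", {
  pts <- mk_patients(10, 10)
  cfg <- cohort_config(symptoms = list(
    fatigue = list(presence = c(active = 0.5, inactive = 0.5),
                   severity_mean = c(active = 9, inactive = 12),
                   slope = c(active = 0, inactive = 0))),
    pro_measures = list(), dropout = c(baseline = 0, m3 = 0, m6 = 0),
    seed = 109)
  pw <- generate_pro_waves(pts, cfg)
  fr <- pw$pro[pw$pro$measure == "sym_fatigue_freq", ]
  base_pts <- fr$patient_id[fr$wave == "baseline"]
  expect_setequal(fr$patient_id[fr$wave == "m6"], base_pts)
  expect_lt(length(base_pts), nrow(pts))
})

test_that("fixture suite is byte-identical under the same seed", {
  td1 <- withr::local_tempdir(); td2 <- withr::local_tempdir()
  p1 <- make_fixture_suite(td1, small_cfg(110))
  p2 <- make_fixture_suite(td2, small_cfg(110))
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
  td3 <- withr::local_tempdir()
  p3 <- make_fixture_suite(td3, small_cfg(111))
  expect_false(identical(readLines(p1[["minutes"]]), readLines(p3[["minutes"]])))
  # the fixture passes the full reader/validator path without error
  m <- read_minute_csv(p2[["minutes"]])
  expect_silent(validate_cohort(m))
})

test_that("configuration rejects out-of-range rates and a missing seed", {
  expect_error(cohort_config(seed = 1, dropout = c(baseline = 0, m3 = 2, m6 = 0)),
               "rates")
  expect_error(cohort_config(), "seed")
})
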