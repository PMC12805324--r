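mk_valid_day <- function(hr, steps = 0, mets = 1, intensity = 0, ...) {
  m <- mk_minutes(hr = hr, steps = steps, mets = mets, intensity = intensity, ...)
  m$hr_eff <- m$hr
  m
}

test_that("sedentary fraction and intensity counting follow the mapping", {
  m <- mk_valid_day(hr = rep(80, 600), intensity = c(rep(0, 400), rep(1, 200)))
  s <- summarize_day(m)
  expect_equal(s$sedentary_frac, 100 * 400 / 600, tolerance = 1e-10)

  m <- mk_valid_day(hr = rep(80, 5), intensity = c(0, 1, 2, 3, 2))
  s <- summarize_day(m)
  expect_equal(s$mvpa_minutes, 3)
  expect_equal(s$light_minutes, 1)

  # METs fallback when intensity is absent: MVPA means > 3 METs
  m <- mk_valid_day(hr = rep(80, 4), intensity = NA, mets = c(2.9, 3.0, 3.1, 7))
  expect_equal(summarize_day(m)$mvpa_minutes, 2)

  expect_null(summarize_day(mk_valid_day(numeric(0))))
})

test_that("class minutes plus unclassifiable minutes partition valid minutes", {
  set.seed(8)
  m <- mk_valid_day(hr = rep(80, 500),
                    intensity = sample(c(0:3, NA), 500, replace = TRUE),
                    mets = sample(c(1, 2, 5), 500, replace = TRUE))
  s <- summarize_day(m)
  cls <- wearcohort:::classify_minutes(m, features_config())
  expect_equal(s$mvpa_minutes + s$light_minutes +
                 sum(cls == "sedentary") + sum(cls == "unclassified"), 500)
})

test_that("sleep features: efficiency, bedtime past midnight, max vs resting HR", {
  sleep <- data.frame(patient_id = "P1",
                      bed_start = as.POSIXct("2024-03-01 23:54:00", tz = "UTC"),
                      bed_end = as.POSIXct("2024-03-02 07:54:00", tz = "UTC"),
                      minutes_asleep = 420, minutes_in_bed = 480,
                      date = as.Date("2024-03-01"))
  m <- mk_valid_day(hr = 70 + (1:120) %% 20)
  s <- summarize_day(m, sleep)
  expect_equal(s$sleep_efficiency, 87.5)        # 420/480, Table-2-style value
  expect_equal(s$hours_asleep, 7)
  expect_equal(s$bedtime_h, 23.9)
  expect_gte(s$max_hr, s$resting_hr)

  # 00:06 bed start reports as 24.1 on the past-midnight scale
  sleep$bed_start <- as.POSIXct("2024-03-02 00:06:00", tz = "UTC")
  expect_equal(summarize_day(m, sleep)$bedtime_h, 24.1)
})

test_that("two-stage averaging weights patients, not days", {
  lab <- data.frame(patient_id = c("A", "B"), label = c("g1", "g1"))
  ds <- data.frame(
    patient_id = c(rep("A", 3), "B"), date = as.Date("2024-03-01") + c(0:2, 0),
    valid_minutes = 1300, is_valid_day = TRUE,
    sedentary_frac = 50, light_minutes = 100,
    mvpa_minutes = c(10, 10, 10, 20), steps = 1000, resting_hr = 70,
    max_hr = 120, bedtime_h = 23, getup_h = 7, hours_asleep = 7,
    sleep_efficiency = 90)
  tab <- cohort_daily_table(ds, lab)
  mv <- tab[tab$measure == "mvpa_minutes", ]
  expect_equal(mv$mean, 15)                 # (10 + 20)/2, not (10*3 + 20)/4
  expect_false(isTRUE(all.equal(mv$mean, mean(ds$mvpa_minutes))))

  # equal day counts: two-stage equals single-stage
  ds2 <- ds[c(1, 4), ]
  tab2 <- cohort_daily_table(ds2, lab)
  expect_equal(tab2$mean[tab2$measure == "mvpa_minutes"],
               mean(ds2$mvpa_minutes))

  # one patient, identical days: SD 0, mean equals the day value
  tab3 <- cohort_daily_table(ds[1:3, ], lab[1, , drop = FALSE])
  expect_equal(tab3$mean[tab3$measure == "mvpa_minutes"], 10)
  expect_equal(tab3$sd[tab3$measure == "mvpa_minutes"], NA_real_)

  expect_error(cohort_daily_table(ds[ds$patient_id == "A", ],
                                  data.frame(patient_id = c("A", "B"),
                                             label = c("g1", "g2"))),
               "empty group")
})

test_that("group means are recovered from a synthetic two-group cohort", {
  cfg <- cohort_config(n_active = 3, n_inactive = 3, fixed_days = 8, seed = 99)
  gen <- generate_cohort_minutes(cfg, inject_artifacts = FALSE)
  val <- validate_cohort(gen$minutes)
  ds <- summarize_days(val, gen$sleep)
  lab <- data.frame(patient_id = gen$truth$patients$patient_id,
                    label = gen$truth$patients$group)
  tab <- cohort_daily_table(ds, lab)
  mv <- tab[tab$measure == "mvpa_minutes", ]
  truth <- tapply(gen$truth$patients$mvpa_daily_mean,
                  gen$truth$patients$group, mean)
  for (g in c("active", "inactive")) {
    expect_lt(abs(mv$mean[mv$group == g] - truth[g]),
              3 * cfg$mvpa_sd_day / sqrt(8))
  }
})
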