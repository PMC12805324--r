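test_that("gap filling takes the mean of adjacent observed heart rates", {
  m <- mk_minutes(hr = c(80, NA, 90), steps = c(0, 30, 0))
  f <- fill_hr_gaps(m)
  expect_equal(f$filled_hr[2], 85)

  # a minute at the device defaults (steps 0, METs 1.0, intensity 0) fails
  # the activity gate and stays nonwear
  m <- mk_minutes(hr = c(80, NA, 90), steps = 0, mets = 1.0, intensity = 0)
  f <- fill_hr_gaps(m)
  expect_true(is.na(f$filled_hr[2]))
  v <- validate_patient(m)
  expect_equal(v$minutes$status[2], "nonwear")

  # multi-minute gap: every gated minute gets the same two-neighbour mean
  m <- mk_minutes(hr = c(60, NA, NA, NA, 70), steps = c(0, 5, 5, 5, 0))
  f <- fill_hr_gaps(m)
  expect_equal(f$filled_hr[2:4], rep(65, 3))
  # oracle agreement on a 20-minute fixture
  set.seed(1)
  m <- mk_minutes(hr = c(60, NA, NA, NA, 70, rep(75, 5), NA, 80, rep(NA, 3),
                         85, 90, NA, 95, 100),
                  steps = sample(0:5, 20, replace = TRUE))
  got <- validate_patient(m)$minutes
  want <- oracle_validate(m)
  expect_equal(got$filled_hr, want$filled_hr)
})

test_that("gap filling respects the same-day and maximum-gap caps", {
  # neighbours on different calendar days never bridge a gap
  m <- mk_minutes(hr = c(70, NA, 72), steps = 10,
                  start = as.POSIXct("2024-03-01 23:59:00", tz = "UTC"))
  f <- fill_hr_gaps(m)
  expect_true(is.na(f$filled_hr[2]))

  # a 61-minute missing span exceeds the default 60-minute cap
  m <- mk_minutes(hr = c(70, rep(NA, 61), 72), steps = 10)
  expect_true(all(is.na(fill_hr_gaps(m)$filled_hr)))
  m <- mk_minutes(hr = c(70, rep(NA, 60), 72), steps = 10)
  expect_equal(sum(!is.na(fill_hr_gaps(m)$filled_hr)), 60)
})

test_that("unsorted or multi-patient input violates the contract", {
  m <- mk_minutes(hr = c(70, 71))
  expect_error(fill_hr_gaps(m[2:1, ]), "contract")
  m2 <- rbind(m, mk_minutes(hr = 70, patient_id = "P2"))
  expect_error(fill_hr_gaps(m2), "single patient")
})

test_that("plausibility exclusion is strictly below 45 / above 205", {
  m <- mk_minutes(hr = c(44, 45, 100, 205, 206))
  v <- validate_patient(m)$minutes
  expect_equal(v$status, c("excluded", "valid_observed", "valid_observed",
                           "valid_observed", "excluded"))
  expect_equal(v$reason[c(1, 5)], c("hr_below_min", "hr_above_max"))
})

test_that("flat-line exclusion needs 11+ consecutive identical minutes", {
  v <- validate_patient(mk_minutes(hr = rep(72, 11)))$minutes
  expect_true(all(v$status == "excluded" & v$reason == "flatline_run"))

  v <- validate_patient(mk_minutes(hr = rep(72, 10)))$minutes
  expect_true(all(v$status == "valid_observed"))

  # maximal-run semantics: the whole 25-minute run goes, length by RLE oracle
  hr <- c(70, rep(60, 25), 71)
  v <- validate_patient(mk_minutes(hr = hr))$minutes
  rle_len <- rle(hr)$lengths[2]
  expect_equal(sum(v$reason == "flatline_run"), rle_len)
  expect_equal(rle_len, 25)

  # a missing minute breaks the run
  hr <- c(rep(72, 6), NA, rep(72, 6))
  v <- validate_patient(mk_minutes(hr = hr, steps = 0))$minutes
  expect_equal(sum(v$reason == "flatline_run"), 0)
})

test_that("valid-day and valid-patient boundaries are strict", {
  day_stream <- function(date, n_valid) {
    hr <- c(rep(80, n_valid), rep(NA, 1440 - n_valid))
    mk_minutes(hr = hr, steps = 0, mets = 1.0,
               start = as.POSIXct(paste(date, "00:00:00"), tz = "UTC"))
  }
  mk_days <- function(valid_counts) {
    do.call(rbind, lapply(seq_along(valid_counts), function(i) {
      day_stream(as.Date("2024-03-01") + i - 1, valid_counts[i])
    }))
  }
  # natural flat-lines would confound: alternate two values
  fix <- function(m) { m$hr[!is.na(m$hr)] <- 80 + seq_len(sum(!is.na(m$hr))) %% 2; m }

  v <- validate_patient(fix(mk_days(rep(1200, 7))))
  expect_true(all(v$days$is_valid_day))
  expect_true(v$is_valid_wear_patient)

  v <- validate_patient(fix(mk_days(c(rep(1200, 6), 1199))))
  expect_equal(sum(v$days$is_valid_day), 6)
  expect_false(v$is_valid_wear_patient)

  expect_false(validate_patient(mk_minutes(numeric(0)))$is_valid_wear_patient)
})

test_that("every minute gets exactly one status and tallies partition", {
  set.seed(42)
  m <- random_stream(3000)
  v <- validate_patient(m)
  expect_true(all(v$minutes$status %in%
                    c("valid_observed", "valid_filled", "excluded", "nonwear")))
  # filled_hr present iff status is valid_filled
  expect_equal(!is.na(v$minutes$filled_hr), v$minutes$status == "valid_filled")
  # per-day tallies partition the non-valid minutes
  d <- v$days
  per_day <- table(as.Date(m$timestamp, tz = "UTC"))
  expect_equal(d$valid_minutes + d$hr_below_min + d$hr_above_max +
                 d$flatline_run + d$nonwear_minutes,
               as.integer(per_day))
})

test_that("validation is idempotent on its own valid output", {
  set.seed(3)
  m <- random_stream(2000)
  v1 <- validate_patient(m)
  keep <- v1$minutes[v1$minutes$status %in% c("valid_observed", "valid_filled"),
                     c("patient_id", "timestamp", "hr_eff", "steps", "mets",
                       "intensity")]
  names(keep)[names(keep) == "hr_eff"] <- "hr"
  v2 <- validate_patient(keep)
  expect_true(all(v2$minutes$status %in% c("valid_observed")))
  expect_equal(nrow(v2$minutes), nrow(keep))
})

test_that("raising hr_max or flatline_min_run never loses valid minutes", {
  set.seed(11)
  m <- random_stream(4000)
  base <- sum(validate_patient(m)$days$valid_minutes)
  for (cfg in list(validation_config(hr_max = 215),
                   validation_config(flatline_min_run = 20))) {
    expect_gte(sum(validate_patient(m, cfg)$days$valid_minutes), base)
  }
})

test_that("flags match the brute-force oracle on random streams", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- random_stream(2000)
    got <- validate_patient(m)$minutes
    want <- oracle_validate(m)
    expect_identical(got$status, want$status, label = paste("seed", seed))
    expect_identical(got$reason, want$reason, label = paste("seed", seed))
    expect_equal(got$filled_hr, want$filled_hr)
  }
})

test_that("configuration rejects inverted or non-positive thresholds", {
  expect_error(validation_config(hr_min = 210, hr_max = 205), "below")
  expect_error(validation_config(valid_day_minutes = 0), "positive")
})
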