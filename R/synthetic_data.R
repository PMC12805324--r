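#' Synthetic cohort configuration
#'
#' Defaults emulate the study conditions the pipeline targets: 41 MVPA-active
#' and 41 MVPA-inactive patients; per-patient valid-day counts lognormal with
#' median 42 days and quartile ratio matching an IQR of 20-70.75; group-level
#' daily MVPA means of 46.9 vs 8.2 minutes (between-patient SDs 31.4/6.3);
#' steps 8966 vs 5744; resting heart rate about 70.7/70.6 bpm; sleep timing
#' and efficiency near the observed group means. Sensor artifacts (missing
#' heart-rate runs, flat-line runs straddling the 11-minute rule, spikes
#' outside the 45-205 plausibility window at roughly the observed exclusion
#' rates) are injected and registered in a ground-truth ledger. PRO waves at
#' baseline/3/6 months carry per-measure group baseline means, a patient
#' random intercept, configurable group-by-time slopes (default: social
#' roles T-score slope 0 for active and +4.21 per 3 months for inactive,
#' i.e. an active-vs-inactive interaction of -4.21) and MCAR wave dropout.
#'
#' @param n_active,n_inactive Patients per phenotype.
#' @param followup_meanlog,followup_sdlog Lognormal parameters for valid-day
#'   counts, clamped to `[min_days, max_days]`.
#' @param min_days,max_days Bounds on per-patient day counts.
#' @param fixed_days If set, every patient gets exactly this many days
#'   (used by small test fixtures).
#' @param mvpa_mean,mvpa_sd_between,mvpa_sd_day,mvpa_slope Daily MVPA
#'   minutes: group means, between-patient SDs, within-patient day-to-day
#'   SD, and per-day group slopes.
#' @param light_mean,light_sd_between Daily lightly-active minutes.
#' @param steps_rate_light,steps_rate_mvpa Mean steps per minute in light
#'   and MVPA minutes.
#' @param resting_hr_mean,resting_hr_sd Resting heart rate by group.
#' @param bedtime_mean,bedtime_sd,getup_mean,getup_sd,sleep_eff_mean,sleep_eff_sd
#'   Sleep timing (hours; bedtime on the >24 = past-midnight scale) and
#'   efficiency (%).
#' @param hr_missing_rest_runs,hr_missing_rest_len,hr_missing_act_runs
#'   Expected per-day counts of rest-time heart-rate deletion runs (mean
#'   length `hr_missing_rest_len`, nonwear) and short activity-time
#'   deletions (length 1-3, fillable).
#' @param flatline_runs_per_day,flatline_len_range Expected flat-line
#'   injections per day and the run-length range (default 8-15, straddling
#'   the 11-minute exclusion rule).
#' @param spike_low_rate,spike_high_rate Per-minute probabilities of
#'   implausible low (<45) and high (>205) heart-rate spikes.
#' @param pro_measures Named list of PRO measure definitions
#'   (`mean = c(active, inactive)`, `sd` ignored in favour of
#'   `patient_sd`/`resid_sd`, `slope = c(active, inactive)` per wave,
#'   `range`, `integer`).
#' @param patient_sd,resid_sd Patient random-intercept SD and residual SD of
#'   PRO scores.
#' @param symptoms Named list of symptom definitions (`presence`,
#'   `severity_mean` by group, `slope` per wave on the severity-mean scale).
#' @param pem_prob Post-exertional-malaise probability by group.
#' @param dropout MCAR wave-dropout probabilities, named
#'   `baseline`/`m3`/`m6`.
#' @param start_date Deployment date shared by all patients.
#' @param seed Mandatory RNG seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_active = 41, n_inactive = 41,
                          followup_meanlog = log(42), followup_sdlog = 0.936,
                          min_days = 7, max_days = 180, fixed_days = NULL,
                          mvpa_mean = c(active = 46.9, inactive = 8.2),
                          mvpa_sd_between = c(active = 31.4, inactive = 6.3),
                          mvpa_sd_day = 12,
                          mvpa_slope = c(active = 0, inactive = 0),
                          light_mean = c(active = 283.2, inactive = 242.1),
                          light_sd_between = c(active = 81, inactive = 82.7),
                          steps_rate_light = 35, steps_rate_mvpa = 110,
                          resting_hr_mean = c(active = 70.7, inactive = 70.6),
                          resting_hr_sd = c(active = 9.0, inactive = 8.7),
                          bedtime_mean = c(active = 23.99, inactive = 24.11),
                          bedtime_sd = c(active = 1.51, inactive = 1.70),
                          getup_mean = c(active = 7.60, inactive = 8.01),
                          getup_sd = c(active = 1.57, inactive = 1.94),
                          sleep_eff_mean = c(active = 87.4, inactive = 87.1),
                          sleep_eff_sd = c(active = 2.7, inactive = 3.7),
                          hr_missing_rest_runs = 1, hr_missing_rest_len = 40,
                          hr_missing_act_runs = 2,
                          flatline_runs_per_day = 1.5,
                          flatline_len_range = c(8, 15),
                          spike_low_rate = 0.0023, spike_high_rate = 1e-5,
                          pro_measures = default_pro_measures(),
                          patient_sd = 8, resid_sd = 6,
                          symptoms = default_symptoms(),
                          pem_prob = c(active = 0.78, inactive = 0.73),
                          dropout = c(baseline = 0, m3 = 0.3, m6 = 0.3),
                          start_date = as.Date("2024-01-01"), seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (any(c(spike_low_rate, spike_high_rate, dropout, pem_prob) < 0 |
            c(spike_low_rate, spike_high_rate, dropout, pem_prob) > 1)) {
    stop("all rates must be in [0, 1]")
  }
  if (n_active < 0 || n_inactive < 0 || n_active + n_inactive < 1) {
    stop("patient counts must be positive")
  }
  structure(mget(names(formals(cohort_config))), class = "cohort_config")
}

#' Default PRO measure definitions (T-score means by phenotype at baseline)
#' @return Named list of measure definitions used by [cohort_config()].
#' @export
default_pro_measures <- function() {
  t_m <- function(a, i, slope_a = 0, slope_i = 0) {
    list(mean = c(active = a, inactive = i),
         slope = c(active = slope_a, inactive = slope_i),
         range = c(20, 80), integer = FALSE)
  }
  list(
    depression_t = t_m(53, 56),
    anxiety_t = t_m(56, 57),
    physical_function_t = t_m(38, 34),
    fatigue_t = t_m(59, 66),
    sleep_disturbance_t = t_m(58, 58),
    pain_interference_t = t_m(60, 65),
    social_roles_t = t_m(47, 40, slope_a = 0, slope_i = 4.21),
    dyspnea_t = t_m(56, 63),
    cognition_t = t_m(46, 41),
    phq2 = list(mean = c(active = 1.3, inactive = 1.9),
                slope = c(active = 0, inactive = 0),
                range = c(0, 6), integer = TRUE),
    gad7 = list(mean = c(active = 6.1, inactive = 8.2),
                slope = c(active = 0, inactive = 0),
                range = c(0, 21), integer = TRUE)
  )
}

#' Default symptom definitions (presence and severity-score means by group)
#' @return Named list used by [cohort_config()].
#' @export
default_symptoms <- function() {
  sym <- function(pa, pi, ma, mi, sa = 0, si = 0) {
    list(presence = c(active = pa, inactive = pi),
         severity_mean = c(active = ma, inactive = mi),
         slope = c(active = sa, inactive = si))
  }
  list(
    fatigue = sym(.88, .95, 9.2, 12.3),
    muscle_pain = sym(.80, .78, 7.0, 8.1),
    joint_pain = sym(.61, .71, 5.6, 7.5),
    unrefreshing_sleep = sym(.71, .83, 7.1, 9.8),
    sleep_problems = sym(.83, .90, 7.1, 10.4, sa = 0, si = -2.06),
    memory = sym(.59, .76, 5.2, 8.1),
    concentration = sym(.63, .85, 5.3, 8.7),
    dizziness = sym(.71, .80, 4.8, 4.4)
  )
}

# draw the per-patient profile table (the phenotype part of the ledger)
generate_patient_profiles <- function(config) {
  n <- config$n_active + config$n_inactive
  group <- rep(c("active", "inactive"), c(config$n_active, config$n_inactive))
  g <- function(par) unname(par[group])
  n_days <- if (!is.null(config$fixed_days)) {
    rep(config$fixed_days, n)
  } else {
    pmin(pmax(round(stats::rlnorm(n, config$followup_meanlog,
                                  config$followup_sdlog)),
              config$min_days), config$max_days)
  }
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    group = group,
    n_days = n_days,
    mvpa_daily_mean = pmax(stats::rnorm(n, g(config$mvpa_mean),
                                        g(config$mvpa_sd_between)), 0),
    light_daily_mean = pmax(stats::rnorm(n, g(config$light_mean),
                                         g(config$light_sd_between)), 30),
    resting_hr = stats::rnorm(n, g(config$resting_hr_mean),
                              g(config$resting_hr_sd)),
    bedtime_h = stats::rnorm(n, g(config$bedtime_mean), g(config$bedtime_sd)),
    getup_h = pmax(stats::rnorm(n, g(config$getup_mean), g(config$getup_sd)), 4),
    sleep_eff = pmin(pmax(stats::rnorm(n, g(config$sleep_eff_mean),
                                       g(config$sleep_eff_sd)), 50), 99),
    stringsAsFactors = FALSE
  )
}

# place `count` non-overlapping runs of the given lengths inside `eligible`
# minute indices; returns a list of integer vectors (possibly fewer runs)
place_runs <- function(eligible, lens, occupied) {
  out <- list()
  for (len in lens) {
    cand <- eligible[!eligible %in% occupied]
    if (length(cand) == 0) break
    starts <- cand[sample.int(length(cand), min(30, length(cand)))]
    for (s in starts) {
      run <- s:(s + len - 1)
      if (all(run %in% eligible) && !any(run %in% occupied)) {
        out[[length(out) + 1]] <- run
        occupied <- c(occupied, run)
        break
      }
    }
  }
  list(runs = out, occupied = occupied)
}

#' Generate one synthetic patient-day of minute-level wearable data
#'
#' Builds 1440 consistent minutes: a sleep window with low heart rate and
#' zero steps, a circadian heart-rate baseline (sinusoid plus AR(1) noise on
#' the patient's resting level), and activity bouts that raise intensity,
#' METs, steps and heart rate jointly (intensity 2-3 always implies METs > 3
#' and elevated steps). Artifacts are then injected and registered: rest-time
#' heart-rate deletions (nonwear), short activity-time deletions (fillable),
#' flat-line runs, and out-of-range spikes. Non-artifact heart rate is kept
#' inside 46-204 bpm so every exclusion on clean streams is ledger-injected.
#'
#' @param profile One row of the patient profile table.
#' @param date Calendar date of the day.
#' @param config A [cohort_config()].
#' @param inject_artifacts Set `FALSE` for clean streams.
#' @return List `minutes` (1440-row minute table), `artifacts` (ledger
#'   rows: type, start minute, length), `true_mvpa` (scheduled MVPA
#'   minutes).
#' @export
generate_minute_stream <- function(profile, date, config,
                                   inject_artifacts = TRUE) {
  n <- 1440
  tmin <- 0:(n - 1)
  getup_min <- round(profile$getup_h * 60) + sample(-15:15, 1)
  bed_h <- profile$bedtime_h + stats::rnorm(1, 0, 0.3)
  bed_min <- if (bed_h >= 24) n else max(round(bed_h * 60), getup_min + 300)
  asleep <- tmin < getup_min | tmin >= bed_min
  wake_idx <- which(!asleep)

  cls <- rep("sedentary", n)
  cls[asleep] <- "sleep"
  true_mvpa <- max(0, round(stats::rnorm(1, profile$mvpa_daily_mean,
                                         config$mvpa_sd_day)))
  true_mvpa <- min(true_mvpa, floor(length(wake_idx) / 3))
  occupied <- integer(0)
  remaining <- true_mvpa
  lens <- integer(0)
  while (remaining > 0) {
    l <- min(remaining, sample(5:15, 1))
    lens <- c(lens, l); remaining <- remaining - l
  }
  pl <- place_runs(wake_idx, lens, occupied)
  mvpa_idx <- unlist(pl$runs)
  true_mvpa <- length(mvpa_idx)          # what actually fitted in the day
  occupied <- pl$occupied
  light_target <- max(0, round(stats::rnorm(1, profile$light_daily_mean, 30)))
  light_target <- min(light_target, length(wake_idx) - true_mvpa)
  remaining <- light_target; lens <- integer(0)
  while (remaining > 0) {
    l <- min(remaining, sample(10:40, 1))
    lens <- c(lens, l); remaining <- remaining - l
  }
  pl <- place_runs(wake_idx, lens, occupied)
  light_idx <- unlist(pl$runs)
  cls[mvpa_idx] <- "mvpa"
  cls[light_idx] <- "light"

  intensity <- integer(n)
  mets <- rep(1.0, n)
  steps <- integer(n)
  hr_add <- numeric(n)
  is_m <- cls == "mvpa"
  vig <- is_m & stats::runif(n) < 0.2
  intensity[is_m] <- 2L; intensity[vig] <- 3L
  mets[is_m & !vig] <- stats::runif(sum(is_m & !vig), 3.2, 6)
  mets[vig] <- stats::runif(sum(vig), 6, 9)
  steps[is_m] <- stats::rpois(sum(is_m), config$steps_rate_mvpa) + 1L
  hr_add[is_m] <- 25 + 4 * mets[is_m]
  is_l <- cls == "light"
  intensity[is_l] <- 1L
  mets[is_l] <- stats::runif(sum(is_l), 1.6, 2.9)
  steps[is_l] <- stats::rpois(sum(is_l), config$steps_rate_light) + 1L
  hr_add[is_l] <- 10
  mets[cls == "sleep"] <- 1.0

  ar <- stats::filter(stats::rnorm(n, 0, 2), 0.85, method = "recursive")
  hr <- profile$resting_hr + 6 + 4 * sin(2 * pi * (tmin / n - 0.6)) +
    as.numeric(ar) + hr_add
  hr[asleep] <- profile$resting_hr - 4 + as.numeric(ar)[asleep]
  # reflect (not clamp) at the physiological floor/ceiling: clamping would
  # pile identical values at the bound and fabricate flat-line runs
  low <- hr < 46
  hr[low] <- 46 + (46 - hr[low])
  high <- hr > 204
  hr[high] <- 204 - (hr[high] - 204)
  hr <- pmin(pmax(round(hr), 46), 204)

  artifacts <- list()
  if (inject_artifacts) {
    occupied_art <- integer(0)
    # nonwear: rest-time deletion runs (fail the activity gate)
    rest_idx <- which(cls %in% c("sleep", "sedentary"))
    n_rest <- stats::rpois(1, config$hr_missing_rest_runs)
    if (n_rest > 0) {
      lens <- pmax(stats::rpois(n_rest, config$hr_missing_rest_len), 5)
      pl <- place_runs(rest_idx, lens, occupied_art)
      for (run in pl$runs) {
        artifacts[[length(artifacts) + 1]] <-
          data.frame(type = "hr_missing_rest", start = run[1],
                     length = length(run))
      }
      occupied_art <- pl$occupied
      hr[unlist(pl$runs)] <- NA
    }
    # fillable: short deletions inside activity bouts
    act_idx <- setdiff(c(mvpa_idx, light_idx), occupied_art)
    n_act <- stats::rpois(1, config$hr_missing_act_runs)
    if (n_act > 0 && length(act_idx)) {
      # keep a neighbour on both sides inside the bout
      inner <- act_idx[(act_idx - 1) %in% act_idx & (act_idx + 1) %in% act_idx]
      pl <- place_runs(inner, sample(1:3, n_act, replace = TRUE), occupied_art)
      for (run in pl$runs) {
        artifacts[[length(artifacts) + 1]] <-
          data.frame(type = "hr_missing_activity", start = run[1],
                     length = length(run))
      }
      occupied_art <- pl$occupied
      hr[unlist(pl$runs)] <- NA
    }
    # flat-line runs on surviving observed heart rate
    obs_idx <- which(!is.na(hr))
    n_fl <- stats::rpois(1, config$flatline_runs_per_day)
    if (n_fl > 0) {
      lr <- config$flatline_len_range
      pl <- place_runs(obs_idx, sample(lr[1]:lr[2], n_fl, replace = TRUE),
                       occupied_art)
      for (run in pl$runs) {
        v <- hr[run[1]]
        hr[run] <- v
        # keep the run maximal: neighbours must differ from the run value
        lo <- run[1] - 1; hi <- run[length(run)] + 1
        if (lo >= 1 && !is.na(hr[lo]) && hr[lo] == v) hr[lo] <- v + 1
        if (hi <= n && !is.na(hr[hi]) && hr[hi] == v) hr[hi] <- v + 1
        artifacts[[length(artifacts) + 1]] <-
          data.frame(type = "flatline", start = run[1], length = length(run))
      }
      occupied_art <- pl$occupied
    }
    # implausible spikes on the remaining observed minutes
    free <- setdiff(which(!is.na(hr)), occupied_art)
    low <- free[stats::runif(length(free)) < config$spike_low_rate]
    hr[low] <- sample(30:44, length(low), replace = TRUE)
    high <- setdiff(free, low)
    high <- high[stats::runif(length(high)) < config$spike_high_rate]
    hr[high] <- sample(206:215, length(high), replace = TRUE)
    for (s in low) {
      artifacts[[length(artifacts) + 1]] <-
        data.frame(type = "spike_low", start = s, length = 1L)
    }
    for (s in high) {
      artifacts[[length(artifacts) + 1]] <-
        data.frame(type = "spike_high", start = s, length = 1L)
    }
  }
  ts <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + tmin * 60
  minutes <- data.frame(
    patient_id = profile$patient_id, timestamp = ts, hr = as.numeric(hr),
    steps = as.integer(steps), mets = mets, intensity = as.integer(intensity),
    stringsAsFactors = FALSE
  )
  art <- if (length(artifacts)) do.call(rbind, artifacts) else
    data.frame(type = character(0), start = integer(0), length = integer(0))
  if (nrow(art)) {
    art$patient_id <- profile$patient_id
    art$date <- date
  }
  list(minutes = minutes, artifacts = art, true_mvpa = true_mvpa)
}

# one sleep-session row consistent with the day's sleep window
generate_sleep_record <- function(profile, date) {
  bed_h <- profile$bedtime_h + stats::rnorm(1, 0, 0.3)
  start <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + bed_h * 3600
  in_bed <- round((24 - bed_h + profile$getup_h) * 60 + stats::rnorm(1, 0, 20))
  in_bed <- max(in_bed, 240)
  asleep <- round(in_bed * profile$sleep_eff / 100)
  data.frame(patient_id = profile$patient_id,
             bed_start = start, bed_end = start + in_bed * 60,
             minutes_asleep = asleep, minutes_in_bed = in_bed,
             date = as.Date(date), stringsAsFactors = FALSE)
}

#' Generate a full synthetic minute-level cohort
#'
#' Seeds the RNG from `config$seed`, draws patient profiles and generates
#' every patient-day with [generate_minute_stream()] plus nightly sleep
#' sessions.
#'
#' @param config A [cohort_config()]. Minute-level generation costs about
#'   1440 rows per patient-day; keep `n_active + n_inactive` and day counts
#'   modest.
#' @param inject_artifacts Passed through to [generate_minute_stream()].
#' @return List `minutes`, `sleep`, `truth` (list: `patients` profile table
#'   with true phenotype inputs, `day_mvpa` per-day scheduled MVPA,
#'   `artifacts` registry).
#' @export
generate_cohort_minutes <- function(config, inject_artifacts = TRUE) {
  set.seed(config$seed)
  profiles <- generate_patient_profiles(config)
  all_min <- list(); all_sleep <- list(); all_art <- list(); day_rows <- list()
  for (i in seq_len(nrow(profiles))) {
    pr <- profiles[i, ]
    dates <- config$start_date + seq_len(pr$n_days) - 1
    for (d in seq_along(dates)) {
      g <- generate_minute_stream(pr, dates[d], config, inject_artifacts)
      all_min[[length(all_min) + 1]] <- g$minutes
      if (nrow(g$artifacts)) all_art[[length(all_art) + 1]] <- g$artifacts
      day_rows[[length(day_rows) + 1]] <-
        data.frame(patient_id = pr$patient_id, date = dates[d],
                   true_mvpa = g$true_mvpa, stringsAsFactors = FALSE)
      all_sleep[[length(all_sleep) + 1]] <- generate_sleep_record(pr, dates[d])
    }
  }
  minutes <- do.call(rbind, all_min)
  rownames(minutes) <- NULL
  list(minutes = minutes,
       sleep = do.call(rbind, all_sleep),
       truth = list(patients = profiles,
                    day_mvpa = do.call(rbind, day_rows),
                    artifacts = if (length(all_art)) do.call(rbind, all_art)
                    else NULL))
}

#' Generate day-level feature series directly (fast path)
#'
#' Skips minute-level simulation: per patient, daily MVPA is the patient
#' mean (drawn from the group distribution) plus a group day-slope and
#' Gaussian day-to-day noise, truncated at 0. Used for trajectory-model and
#' feature-recovery testing at realistic cohort sizes.
#'
#' @param config A [cohort_config()].
#' @param truncate_nonneg Truncate negative day values at 0 (default).
#' @return List `series` (`patient_id, group, day, value`) and `truth`
#'   (patient profiles).
#' @export
generate_day_series <- function(config, truncate_nonneg = TRUE) {
  set.seed(config$seed)
  profiles <- generate_patient_profiles(config)
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    pr <- profiles[i, ]
    d <- seq_len(pr$n_days) - 1
    slope <- unname(config$mvpa_slope[pr$group])
    v <- pr$mvpa_daily_mean + slope * d + stats::rnorm(length(d), 0, config$mvpa_sd_day)
    if (truncate_nonneg) v <- pmax(v, 0)
    data.frame(patient_id = pr$patient_id, group = pr$group, day = d,
               value = v, stringsAsFactors = FALSE)
  })
  list(series = do.call(rbind, rows), truth = profiles)
}

#' Generate PRO waves for a cohort
#'
#' Per measure: score = group baseline mean + patient random intercept +
#' group slope x wave + residual noise, truncated to the documented range
#' (rounded for integer-scored instruments). Symptom frequency and intensity
#' ratings are drawn to match the target severity-score means; follow-up
#' symptom items are only generated for symptoms present at baseline
#' (baseline-gated follow-up). Whole patient-waves are deleted MCAR at the
#' configured per-wave rates.
#'
#' @param patients Profile table (needs `patient_id`, `group`), e.g. from
#'   [generate_cohort_minutes()] truth or [generate_day_series()].
#' @param config A [cohort_config()].
#' @param reseed Seed the RNG from `config$seed` (default `TRUE`; set
#'   `FALSE` when calling inside an already-seeded stream).
#' @return List `pro` (long table `patient_id, wave, measure, value`) and
#'   `truth` (list with per-measure group slopes and the dropout pattern).
#' @export
generate_pro_waves <- function(patients, config, reseed = TRUE) {
  if (reseed) set.seed(config$seed)
  waves <- c("baseline", "m3", "m6")
  n <- nrow(patients)
  dropped <- matrix(FALSE, n, 3, dimnames = list(patients$patient_id, waves))
  for (w in 1:3) {
    dropped[, w] <- stats::runif(n) < config$dropout[waves[w]]
  }
  rows <- list()
  for (m in names(config$pro_measures)) {
    def <- config$pro_measures[[m]]
    b <- stats::rnorm(n, 0, config$patient_sd)
    for (w in 1:3) {
      keep <- !dropped[, w]
      if (!any(keep)) next
      g <- patients$group[keep]
      mu <- unname(def$mean[g]) + unname(def$slope[g]) * (w - 1)
      v <- mu + b[keep] + stats::rnorm(sum(keep), 0, config$resid_sd)
      v <- pmin(pmax(v, def$range[1]), def$range[2])
      if (isTRUE(def$integer)) v <- round(v)
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = patients$patient_id[keep], wave = waves[w],
        measure = m, value = v, stringsAsFactors = FALSE)
    }
  }
  for (s in names(config$symptoms)) {
    def <- config$symptoms[[s]]
    present <- stats::runif(n) < unname(def$presence[patients$group])
    for (w in 1:3) {
      keep <- present & !dropped[, w]      # baseline-gated follow-up
      if (!any(keep)) next
      g <- patients$group[keep]
      mu <- pmax(unname(def$severity_mean[g]) + unname(def$slope[g]) * (w - 1), 0)
      q <- pmin(sqrt(mu / 16), 1)          # E[freq x int] = 16 q^2 = mu
      fr <- stats::rbinom(sum(keep), 4, q)
      it <- stats::rbinom(sum(keep), 4, q)
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = patients$patient_id[keep], wave = waves[w],
        measure = paste0("sym_", s, "_freq"), value = fr,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = patients$patient_id[keep], wave = waves[w],
        measure = paste0("sym_", s, "_int"), value = it,
        stringsAsFactors = FALSE)
    }
  }
  keep <- !dropped[, 1]
  if (any(keep)) {
    rows[[length(rows) + 1]] <- data.frame(
      patient_id = patients$patient_id[keep], wave = "baseline",
      measure = "pem",
      value = as.numeric(stats::runif(sum(keep)) <
                           unname(config$pem_prob[patients$group[keep]])),
      stringsAsFactors = FALSE)
  }
  pro <- do.call(rbind, rows)
  pro <- pro[order(pro$patient_id, pro$wave, pro$measure), ]
  rownames(pro) <- NULL
  slopes <- lapply(config$pro_measures, `[[`, "slope")
  list(pro = pro,
       truth = list(slopes = slopes, dropped = dropped,
                    interaction = vapply(slopes, function(s) {
                      unname(s["active"] - s["inactive"])
                    }, numeric(1))))
}

#' Write a deterministic on-disk mini-cohort fixture
#'
#' Generates a small cohort (default 2 active + 1 inactive patients, 10 days
#' each) and writes the three CSVs the readers consume: a Fitabase-style
#' joined minute file (METs stored x10), a sleep-session file and a long
#' PRO table. Regeneration with the same seed is byte-identical.
#'
#' @param dir Output directory (created if needed).
#' @param config A [cohort_config()]; defaults to the small fixture cohort.
#' @return Named paths of the written files, invisibly.
#' @export
make_fixture_suite <- function(dir, config = cohort_config(
                                 n_active = 2, n_inactive = 1,
                                 fixed_days = 10, seed = 20240101)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_cohort_minutes(config)
  pro <- generate_pro_waves(gen$truth$patients, config, reseed = FALSE)
  m <- gen$minutes
  minute_csv <- data.frame(
    Id = m$patient_id,
    ActivityMinute = format(m$timestamp, "%Y-%m-%d %H:%M:%S"),
    HeartRate = m$hr,
    Steps = m$steps,
    METs = as.integer(round(m$mets * 10)),
    Intensity = m$intensity
  )
  paths <- c(minutes = file.path(dir, "minutes.csv"),
             sleep = file.path(dir, "sleep.csv"),
             pro = file.path(dir, "pro.csv"))
  utils::write.csv(minute_csv, paths["minutes"], row.names = FALSE,
                   quote = FALSE, na = "")
  s <- gen$sleep
  sleep_csv <- data.frame(
    Id = s$patient_id,
    BedStart = format(s$bed_start, "%Y-%m-%d %H:%M:%S"),
    BedEnd = format(s$bed_end, "%Y-%m-%d %H:%M:%S"),
    MinutesAsleep = s$minutes_asleep,
    MinutesInBed = s$minutes_in_bed
  )
  utils::write.csv(sleep_csv, paths["sleep"], row.names = FALSE,
                   quote = FALSE, na = "")
  utils::write.csv(pro$pro[, c("patient_id", "wave", "measure", "value")],
                   paths["pro"], row.names = FALSE, quote = FALSE, na = "")
  attr(paths, "truth") <- gen$truth
  invisible(paths)
}
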