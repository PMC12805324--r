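# builders and independent oracles shared across the suite

# minute table builder: hr/steps/mets/intensity vectors are recycled
mk_minutes <- function(hr, steps = 0, mets = 1, intensity = 0,
                       patient_id = "P1",
                       start = as.POSIXct("2024-03-01 08:00:00", tz = "UTC"),
                       gap_after = integer(0)) {
  n <- length(hr)
  if (n == 0) {
    return(data.frame(patient_id = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      hr = numeric(0), steps = numeric(0), mets = numeric(0),
                      intensity = numeric(0), stringsAsFactors = FALSE))
  }
  offs <- seq_len(n) - 1
  # gap_after: indices after which one extra minute is skipped entirely
  for (g in sort(gap_after)) offs[(g + 1):n] <- offs[(g + 1):n] + 1
  data.frame(patient_id = patient_id, timestamp = start + offs * 60,
             hr = as.numeric(hr), steps = as.numeric(steps),
             mets = as.numeric(mets), intensity = as.numeric(intensity),
             stringsAsFactors = FALSE)
}

# independent single-pass re-implementation of the validation rules with
# explicit loops; deliberately naive, used as the oracle
oracle_validate <- function(minutes, config = validation_config()) {
  n <- nrow(minutes)
  tm <- round(as.numeric(minutes$timestamp) / 60)
  day <- as.Date(minutes$timestamp, tz = "UTC")
  status <- character(n); reason <- character(n)
  hr_eff <- minutes$hr
  filled <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!is.na(minutes$hr[i])) {
      status[i] <- "valid_observed"; reason[i] <- "none"
      next
    }
    gate <- (!is.na(minutes$steps[i]) && minutes$steps[i] > config$steps_gate) ||
      (!is.na(minutes$mets[i]) && minutes$mets[i] > config$met_gate) ||
      (!is.na(minutes$intensity[i]) && minutes$intensity[i] > config$intensity_gate)
    prev <- NA_integer_; nxt <- NA_integer_
    if (gate) {
      j <- i - 1
      while (j >= 1) {
        if (day[j] != day[i]) break
        if (!is.na(minutes$hr[j])) { prev <- j; break }
        j <- j - 1
      }
      j <- i + 1
      while (j <= n) {
        if (day[j] != day[i]) break
        if (!is.na(minutes$hr[j])) { nxt <- j; break }
        j <- j + 1
      }
    }
    if (!is.na(prev) && !is.na(nxt) &&
        (tm[nxt] - tm[prev] - 1) <= config$max_fill_gap) {
      filled[i] <- (minutes$hr[prev] + minutes$hr[nxt]) / 2
      hr_eff[i] <- filled[i]
      status[i] <- "valid_filled"; reason[i] <- "none"
    } else {
      status[i] <- "nonwear"; reason[i] <- "no_signal"
    }
  }
  # plausibility (strict below/above), on observed and filled values
  for (i in seq_len(n)) {
    v <- if (config$exclude_filled) hr_eff[i] else minutes$hr[i]
    if (status[i] %in% c("valid_observed", "valid_filled") && !is.na(v)) {
      if (v < config$hr_min) { status[i] <- "excluded"; reason[i] <- "hr_below_min" }
      if (v > config$hr_max) { status[i] <- "excluded"; reason[i] <- "hr_above_max" }
    }
  }
  # flat lines: maximal runs of identical observed values on adjacent minutes
  i <- 1
  while (i <= n) {
    if (is.na(minutes$hr[i])) { i <- i + 1; next }
    j <- i
    while (j + 1 <= n && !is.na(minutes$hr[j + 1]) &&
           minutes$hr[j + 1] == minutes$hr[i] && (tm[j + 1] - tm[j]) == 1) {
      j <- j + 1
    }
    if (j - i + 1 >= config$flatline_min_run) {
      for (k in i:j) {
        if (status[k] != "excluded") {
          status[k] <- "excluded"; reason[k] <- "flatline_run"
        }
      }
    }
    i <- j + 1
  }
  filled[status != "valid_filled"] <- NA_real_
  data.frame(status = status, reason = reason, filled_hr = filled,
             stringsAsFactors = FALSE)
}

# random adversarial minute stream exercising every rule at once
random_stream <- function(n, patient_id = "P1",
                          start = as.POSIXct("2024-03-01 00:00:00", tz = "UTC")) {
  hr <- sample(c(38:212, NA), n, replace = TRUE,
               prob = c(rep(1, 175), 60))
  # inject runs of identical values with random lengths
  k <- max(1, round(n / 200))
  for (s in sample.int(n - 30, k)) {
    len <- sample(5:20, 1)
    hr[s:(s + len - 1)] <- hr[s]
  }
  steps <- sample(c(0, 0, 0, 1, 40, 120), n, replace = TRUE)
  mets <- sample(c(0.9, 1.0, 1.2, 3.5, 7), n, replace = TRUE)
  intensity <- sample(0:3, n, replace = TRUE, prob = c(6, 2, 1, 1))
  # random missing rows (absent minutes) break adjacency
  keep <- sort(sample.int(round(n * 1.06), n))
  data.frame(patient_id = patient_id, timestamp = start + keep * 60,
             hr = hr, steps = steps, mets = mets, intensity = intensity,
             stringsAsFactors = FALSE)
}

# small standard cohort pieces used by several model tests
mk_patients <- function(n_active = 41, n_inactive = 41) {
  data.frame(patient_id = sprintf("P%03d", seq_len(n_active + n_inactive)),
             group = rep(c("active", "inactive"), c(n_active, n_inactive)),
             stringsAsFactors = FALSE)
}

# a cohort config carrying only the social-roles measure (fast PRO draws)
social_roles_config <- function(seed, interaction = -4.21, dropout = 0.3) {
  cohort_config(
    pro_measures = list(social_roles_t = list(
      mean = c(active = 47, inactive = 40),
      slope = c(active = 0, inactive = -interaction),
      range = c(20, 80), integer = FALSE)),
    symptoms = list(),
    dropout = c(baseline = 0, m3 = dropout, m6 = dropout),
    seed = seed)
}

sim_social_roles <- function(seed, interaction = -4.21, dropout = 0.3) {
  pts <- mk_patients()
  pw <- generate_pro_waves(pts, social_roles_config(seed, interaction, dropout))
  d <- pw$pro[pw$pro$measure == "social_roles_t", ]
  d$group <- pts$group[match(d$patient_id, pts$patient_id)]
  d
}

# correlated 3-variable normal matrix with MCAR or value-driven (MNAR)
# missingness, for the missingness-mechanism tests
mk_missing_matrix <- function(n = 200, rho = 0.5, rate = 0.3,
                              mechanism = c("mcar", "mnar")) {
  mechanism <- match.arg(mechanism)
  S <- matrix(rho, 3, 3); diag(S) <- 1
  X <- matrix(stats::rnorm(n * 3), n, 3) %*% chol(S)
  if (mechanism == "mcar") {
    X[matrix(stats::runif(n * 3) < rate, n, 3)] <- NA
  } else {
    for (j in 2:3) X[, j][X[, j] > stats::quantile(X[, j], 1 - rate)] <- NA
  }
  X
}
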