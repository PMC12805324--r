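#' Wear-time validation configuration
#'
#' Thresholds for the minute-level validation pipeline. Defaults follow the
#' established heart-rate-based wear-time rules for Fitbit-class devices:
#' heart rates below 45 or above 205 bpm are physiologically implausible and
#' excluded; runs of identical heart-rate values lasting 11 or more
#' consecutive minutes are treated as sensor artifacts; a day is a valid wear
#' day with at least 1200 valid minutes (20 hours); a patient has valid wear
#' with at least 7 valid wear days over all available data.
#'
#' A minute with missing heart rate is only eligible for gap filling when it
#' shows activity above device defaults: steps above `steps_gate` (0), METs
#' above `met_gate` (1.0), or intensity above `intensity_gate`. The device
#' default intensity is 0 (sedentary), so the gate defaults to
#' `intensity > 0`; set `intensity_gate = 1` for the stricter reading.
#'
#' @param hr_min,hr_max Plausibility window in bpm (exclusion is strictly
#'   below/above, so 45 and 205 themselves are retained).
#' @param flatline_min_run Minimum run length (minutes) of identical observed
#'   heart-rate values that is excluded as a flat line.
#' @param steps_gate,met_gate,intensity_gate Activity gate: a missing-HR
#'   minute qualifies for filling when any signal is strictly above its gate.
#' @param valid_day_minutes Valid minutes needed for a valid wear day.
#' @param valid_patient_days Valid days needed for a valid wear patient.
#' @param max_fill_gap Longest gap (minutes of consecutive missing HR)
#'   bridged by gap filling; longer gaps stay nonwear.
#' @param exclude_filled Apply the plausibility window to filled values too
#'   (the pipeline's documented order: fill, then plausibility, then
#'   flat-line). Set `FALSE` to restrict exclusion to observed values.
#' @return A list of class `validation_config`.
#' @export
validation_config <- function(hr_min = 45, hr_max = 205,
                              flatline_min_run = 11,
                              steps_gate = 0, met_gate = 1.0,
                              intensity_gate = 0,
                              valid_day_minutes = 1200,
                              valid_patient_days = 7,
                              max_fill_gap = 60,
                              exclude_filled = TRUE) {
  if (hr_min >= hr_max) stop("hr_min must be below hr_max")
  vals <- c(hr_min = hr_min, hr_max = hr_max,
            flatline_min_run = flatline_min_run,
            valid_day_minutes = valid_day_minutes,
            valid_patient_days = valid_patient_days, max_fill_gap = max_fill_gap)
  if (any(vals <= 0)) stop("all thresholds must be positive")
  structure(list(hr_min = hr_min, hr_max = hr_max,
                 flatline_min_run = flatline_min_run,
                 steps_gate = steps_gate, met_gate = met_gate,
                 intensity_gate = intensity_gate,
                 valid_day_minutes = valid_day_minutes,
                 valid_patient_days = valid_patient_days,
                 max_fill_gap = max_fill_gap,
                 exclude_filled = exclude_filled),
            class = "validation_config")
}

check_single_sorted <- function(minutes) {
  if (length(unique(minutes$patient_id)) > 1) {
    stop("contract error: minutes must belong to a single patient")
  }
  if (is.unsorted(as.numeric(minutes$timestamp), strictly = TRUE)) {
    stop("contract error: minutes must be sorted by time with unique timestamps")
  }
  invisible(TRUE)
}

# activity gate: any signal strictly above its device default
activity_gate <- function(minutes, config) {
  gate <- rep(FALSE, nrow(minutes))
  g <- function(v, thr) !is.na(v) & v > thr
  gate | g(minutes$steps, config$steps_gate) |
    g(minutes$mets, config$met_gate) |
    g(minutes$intensity, config$intensity_gate)
}

#' Fill heart-rate gaps from adjacent observed minutes
#'
#' A minute with missing heart rate receives the arithmetic mean of the
#' nearest preceding and nearest following observed heart rates if and only
#' if it passes the activity gate. Neighbours must fall within the same
#' calendar day, fills never seed further fills (only observed values serve
#' as neighbours), and gaps longer than `config$max_fill_gap` minutes are
#' left unfilled (nonwear).
#'
#' @param minutes One patient's minute table, sorted by time.
#' @param config A [validation_config()].
#' @return `minutes` with columns `filled_hr` (the fill value or `NA`) and
#'   `gate_pass` added.
#' @export
fill_hr_gaps <- function(minutes, config = validation_config()) {
  check_single_sorted(minutes)
  n <- nrow(minutes)
  minutes$gate_pass <- activity_gate(minutes, config)
  minutes$filled_hr <- NA_real_
  if (n == 0) return(minutes)
  tm <- round(as.numeric(minutes$timestamp) / 60)
  day <- as.Date(minutes$timestamp, tz = "UTC")
  obs <- which(!is.na(minutes$hr))
  gaps <- which(is.na(minutes$hr))
  if (length(obs) == 0 || length(gaps) == 0) return(minutes)
  pos <- findInterval(tm[gaps], tm[obs])
  prev <- ifelse(pos >= 1, obs[pmax(pos, 1)], NA_integer_)
  nxt <- ifelse(pos + 1 <= length(obs), obs[pmin(pos + 1, length(obs))], NA_integer_)
  ok <- !is.na(prev) & !is.na(nxt)
  ok[ok] <- day[prev[ok]] == day[gaps[ok]] & day[nxt[ok]] == day[gaps[ok]] &
    (tm[nxt[ok]] - tm[prev[ok]] - 1) <= config$max_fill_gap
  ok <- ok & minutes$gate_pass[gaps]
  fill_idx <- gaps[ok]
  minutes$filled_hr[fill_idx] <- (minutes$hr[prev[ok]] + minutes$hr[nxt[ok]]) / 2
  minutes
}

#' Flag heart rates outside the plausibility window
#'
#' Heart rates strictly below `hr_min` or strictly above `hr_max` are
#' excluded; the bounds themselves are retained. Applies to observed values
#' and, when `config$exclude_filled` is `TRUE`, to filled values as well.
#'
#' @param minutes Minute table carrying `filled_hr` (run [fill_hr_gaps()]
#'   first, or the column may be absent for observed-only checking).
#' @param config A [validation_config()].
#' @return `minutes` with a logical `implausible` column and `excl_reason`
#'   (`"hr_below_min"`, `"hr_above_max"`, or `NA`).
#' @export
exclude_implausible <- function(minutes, config = validation_config()) {
  hr_eff <- minutes$hr
  if (config$exclude_filled && "filled_hr" %in% names(minutes)) {
    hr_eff[is.na(hr_eff)] <- minutes$filled_hr[is.na(hr_eff)]
  }
  minutes$excl_reason <- NA_character_
  minutes$excl_reason[!is.na(hr_eff) & hr_eff < config$hr_min] <- "hr_below_min"
  minutes$excl_reason[!is.na(hr_eff) & hr_eff > config$hr_max] <- "hr_above_max"
  minutes$implausible <- !is.na(minutes$excl_reason)
  minutes
}

# run ids over observed-HR minutes: a run breaks on a missing minute
# (timestamp discontinuity or NA heart rate) or any value change
flatline_run_ids <- function(tm, hr) {
  n <- length(hr)
  if (n == 0) return(integer(0))
  newrun <- rep(TRUE, n)
  if (n > 1) {
    same <- !is.na(hr[-1]) & !is.na(hr[-n]) &
      hr[-1] == hr[-n] & (tm[-1] - tm[-n]) == 1
    newrun[-1] <- !same
  }
  cumsum(newrun)
}

#' Flag flat-line runs of identical observed heart rate
#'
#' Every minute of a maximal run of identical observed heart-rate values
#' lasting at least `config$flatline_min_run` consecutive (timestamp-
#' adjacent) minutes is excluded as non-physiological. Missing minutes break
#' a run, and filled values do not participate (fills are constant by
#' construction).
#'
#' @param minutes One patient's minute table, sorted by time.
#' @param config A [validation_config()].
#' @return `minutes` with a logical `flatline` column.
#' @export
exclude_flatlines <- function(minutes, config = validation_config()) {
  check_single_sorted(minutes)
  tm <- round(as.numeric(minutes$timestamp) / 60)
  ids <- flatline_run_ids(tm, minutes$hr)
  minutes$flatline <- FALSE
  if (length(ids)) {
    len <- ave(seq_along(ids), ids, FUN = length)
    minutes$flatline <- !is.na(minutes$hr) & len >= config$flatline_min_run
  }
  minutes
}

#' Validate one patient's minute stream
#'
#' Runs the full minute-level pipeline in its documented order: wear
#' detection (observed heart rate = candidate valid wear), activity-gated gap
#' filling, plausibility-window exclusion, flat-line exclusion, then daily
#' tallies. Every minute ends with exactly one status:
#' `valid_observed`, `valid_filled`, `excluded` (reason `hr_below_min`,
#' `hr_above_max` or `flatline_run`) or `nonwear` (reason `no_signal`).
#'
#' @param minutes One patient's full minute stream (sorted by time).
#' @param config A [validation_config()].
#' @return A list with `minutes` (flagged table with `status`, `reason`,
#'   `filled_hr`, `hr_eff`), `days` (per-day verdicts: `valid_minutes`,
#'   `is_valid_day`, per-reason exclusion tallies, `nonwear_minutes`) and
#'   `is_valid_wear_patient`.
#' @export
validate_patient <- function(minutes, config = validation_config()) {
  if (nrow(minutes) == 0) {
    days <- data.frame(patient_id = character(0), date = as.Date(character(0)),
                       valid_minutes = integer(0), is_valid_day = logical(0),
                       hr_below_min = integer(0), hr_above_max = integer(0),
                       flatline_run = integer(0), nonwear_minutes = integer(0))
    return(list(minutes = minutes, days = days, is_valid_wear_patient = FALSE))
  }
  check_single_sorted(minutes)
  m <- fill_hr_gaps(minutes, config)
  m <- exclude_implausible(m, config)
  fl <- exclude_flatlines(m, config)$flatline

  status <- ifelse(!is.na(m$hr), "valid_observed",
                   ifelse(!is.na(m$filled_hr), "valid_filled", "nonwear"))
  reason <- ifelse(status == "nonwear", "no_signal", "none")
  excl <- m$implausible & status != "nonwear"
  status[excl] <- "excluded"
  reason[excl] <- m$excl_reason[excl]
  take_fl <- fl & status %in% c("valid_observed", "valid_filled")
  status[take_fl] <- "excluded"
  reason[take_fl] <- "flatline_run"

  m$status <- status
  m$reason <- reason
  m$hr_eff <- ifelse(!is.na(m$hr), m$hr, m$filled_hr)
  # invariant: filled_hr present iff status is valid_filled
  m$filled_hr[m$status != "valid_filled"] <- NA_real_
  m$implausible <- NULL
  m$excl_reason <- NULL
  m$flatline <- NULL

  day <- as.Date(m$timestamp, tz = "UTC")
  tally <- function(flag) as.integer(tapply(flag, day, sum))
  days <- data.frame(
    patient_id = m$patient_id[1],
    date = as.Date(names(tapply(rep(1, nrow(m)), day, sum))),
    valid_minutes = tally(m$status %in% c("valid_observed", "valid_filled")),
    hr_below_min = tally(m$reason == "hr_below_min"),
    hr_above_max = tally(m$reason == "hr_above_max"),
    flatline_run = tally(m$reason == "flatline_run"),
    nonwear_minutes = tally(m$status == "nonwear"),
    stringsAsFactors = FALSE
  )
  days$is_valid_day <- days$valid_minutes >= config$valid_day_minutes
  days <- days[, c("patient_id", "date", "valid_minutes", "is_valid_day",
                   "hr_below_min", "hr_above_max", "flatline_run",
                   "nonwear_minutes")]
  list(minutes = m, days = days,
       is_valid_wear_patient = sum(days$is_valid_day) >= config$valid_patient_days)
}

#' Validate a whole cohort's minute table
#'
#' @param minutes Minute table for any number of patients.
#' @param config A [validation_config()].
#' @return A list with `minutes` (flagged), `days` (all patients' day
#'   verdicts), `patients` (data.frame `patient_id`, `n_valid_days`,
#'   `is_valid_wear_patient`) and `exclusion_tally` (cohort totals per
#'   status/reason).
#' @export
validate_cohort <- function(minutes, config = validation_config()) {
  split_m <- split(minutes, minutes$patient_id)
  res <- lapply(split_m, validate_patient, config = config)
  flagged <- do.call(rbind, lapply(res, `[[`, "minutes"))
  days <- do.call(rbind, lapply(res, `[[`, "days"))
  rownames(flagged) <- rownames(days) <- NULL
  patients <- data.frame(
    patient_id = names(res),
    n_valid_days = vapply(res, function(r) sum(r$days$is_valid_day), integer(1)),
    is_valid_wear_patient = vapply(res, `[[`, logical(1), "is_valid_wear_patient"),
    stringsAsFactors = FALSE
  )
  rownames(patients) <- NULL
  tally <- list(
    minutes_processed = nrow(flagged),
    valid_observed = sum(flagged$status == "valid_observed"),
    valid_filled = sum(flagged$status == "valid_filled"),
    hr_below_min = sum(flagged$reason == "hr_below_min"),
    hr_above_max = sum(flagged$reason == "hr_above_max"),
    flatline_run = sum(flagged$reason == "flatline_run"),
    nonwear = sum(flagged$status == "nonwear")
  )
  obs <- sum(!is.na(flagged$hr))
  tally$pct_hr_below_min <- if (obs > 0) 100 * tally$hr_below_min / obs else NA_real_
  tally$pct_hr_above_max <- if (obs > 0) 100 * tally$hr_above_max / obs else NA_real_
  tally$pct_flatline <- if (obs > 0) 100 * tally$flatline_run / obs else NA_real_
  list(minutes = flagged, days = days, patients = patients,
       exclusion_tally = tally)
}
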