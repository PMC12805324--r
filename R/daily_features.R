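#' Daily feature configuration
#'
#' @param mvpa_intensity_min Lowest device intensity code counted as MVPA
#'   (default 2: "fairly active" and "very active" minutes). MVPA is activity
#'   above 3 METs; device codes 2-3 carry that meaning on Fitbit-class
#'   trackers.
#' @param mvpa_met_fallback METs threshold used when intensity is absent
#'   (a minute with METs strictly above this counts as MVPA).
#' @param resting_roll_min Window (minutes) of the rolling heart-rate mean
#'   whose minimum serves as resting heart rate when no daily value is given.
#' @return A list of class `features_config`.
#' @export
features_config <- function(mvpa_intensity_min = 2, mvpa_met_fallback = 3.0,
                            resting_roll_min = 30) {
  stopifnot(mvpa_intensity_min %in% 1:3, mvpa_met_fallback > 0,
            resting_roll_min >= 1)
  structure(list(mvpa_intensity_min = mvpa_intensity_min,
                 mvpa_met_fallback = mvpa_met_fallback,
                 resting_roll_min = resting_roll_min),
            class = "features_config")
}

# minute-class helper shared by summarize_day and tests:
# MVPA = intensity >= mvpa_intensity_min, falling back to METs > 3 when
# intensity is absent; light = intensity 1; sedentary = intensity 0
classify_minutes <- function(minutes, config) {
  cls <- rep("unclassified", nrow(minutes))
  has_int <- !is.na(minutes$intensity)
  cls[has_int & minutes$intensity >= config$mvpa_intensity_min] <- "mvpa"
  cls[has_int & minutes$intensity == 1] <- "light"
  cls[has_int & minutes$intensity == 0] <- "sedentary"
  fallback <- !has_int & !is.na(minutes$mets)
  cls[fallback & minutes$mets > config$mvpa_met_fallback] <- "mvpa"
  cls
}

hours_since_prior_midnight <- function(ts) {
  h <- as.numeric(format(ts, "%H")) + as.numeric(format(ts, "%M")) / 60
  ifelse(h < 12, h + 24, h)  # bedtimes after midnight print as >24 (00:06 -> 24.1)
}

#' Summarise one patient-day of valid minutes into behavioural features
#'
#' @param valid_minutes The day's valid minutes (status `valid_observed` or
#'   `valid_filled`) with `hr_eff`, `steps`, `mets`, `intensity`.
#' @param sleep_record Optional single sleep session row (from
#'   [read_sleep_csv()] or the generator) assigned to this date.
#' @param resting_hr Optional device-supplied daily resting heart rate; when
#'   absent the minimum `resting_roll_min`-minute rolling mean of valid heart
#'   rate is used.
#' @param config A [features_config()].
#' @return One-row day-summary data.frame, or `NULL` for zero valid minutes.
#' @export
summarize_day <- function(valid_minutes, sleep_record = NULL,
                          resting_hr = NULL, config = features_config()) {
  n <- nrow(valid_minutes)
  if (n == 0) return(NULL)
  cls <- classify_minutes(valid_minutes, config)
  sed <- sum(cls == "sedentary")
  hr <- valid_minutes$hr_eff
  if (is.null(resting_hr)) {
    k <- config$resting_roll_min
    resting_hr <- if (n >= k) {
      cs <- cumsum(c(0, hr))
      min((cs[(k + 1):(n + 1)] - cs[1:(n - k + 1)]) / k)
    } else mean(hr)
  }
  out <- data.frame(
    patient_id = valid_minutes$patient_id[1],
    date = as.Date(valid_minutes$timestamp[1], tz = "UTC"),
    valid_minutes = n,
    is_valid_day = NA,
    sedentary_frac = 100 * sed / n,
    light_minutes = sum(cls == "light"),
    mvpa_minutes = sum(cls == "mvpa"),
    steps = sum(valid_minutes$steps, na.rm = TRUE),
    resting_hr = resting_hr,
    max_hr = max(hr),
    bedtime_h = NA_real_, getup_h = NA_real_,
    hours_asleep = NA_real_, sleep_efficiency = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(sleep_record) && nrow(sleep_record) > 0) {
    s <- sleep_record[which.max(sleep_record$minutes_in_bed), ]
    out$bedtime_h <- hours_since_prior_midnight(s$bed_start)
    gh <- as.numeric(format(s$bed_end, "%H")) +
      as.numeric(format(s$bed_end, "%M")) / 60
    out$getup_h <- gh
    out$hours_asleep <- s$minutes_asleep / 60
    out$sleep_efficiency <- 100 * s$minutes_asleep / s$minutes_in_bed
  }
  out
}

#' Summarise a validated cohort into day summaries
#'
#' @param validated Result of [validate_cohort()] (or a list with `minutes`
#'   and `days`).
#' @param sleep Optional sleep-session table from [read_sleep_csv()].
#' @param daily_rhr Optional data.frame `patient_id, date, resting_hr` of
#'   device-supplied daily resting heart rates.
#' @param config A [features_config()].
#' @return Day-summary data.frame (one row per patient-day with at least one
#'   valid minute), with `is_valid_day` joined from the day verdicts.
#' @export
summarize_days <- function(validated, sleep = NULL, daily_rhr = NULL,
                           config = features_config()) {
  m <- validated$minutes
  m <- m[m$status %in% c("valid_observed", "valid_filled"), , drop = FALSE]
  if (nrow(m) == 0) {
    return(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(day_summary_columns()))),
      day_summary_columns()))
  }
  m$date <- as.Date(m$timestamp, tz = "UTC")
  key <- interaction(m$patient_id, m$date, drop = TRUE)
  rows <- lapply(split(m, key), function(dm) {
    pid <- dm$patient_id[1]; dt <- dm$date[1]
    sl <- if (!is.null(sleep)) {
      sleep[sleep$patient_id == pid & sleep$date == dt, , drop = FALSE]
    } else NULL
    rhr <- if (!is.null(daily_rhr)) {
      v <- daily_rhr$resting_hr[daily_rhr$patient_id == pid & daily_rhr$date == dt]
      if (length(v)) v[1] else NULL
    } else NULL
    summarize_day(dm, sl, rhr, config)
  })
  out <- do.call(rbind, rows)
  vd <- validated$days
  idx <- match(paste(out$patient_id, out$date),
               paste(vd$patient_id, vd$date))
  out$is_valid_day <- vd$is_valid_day[idx]
  out <- out[order(out$patient_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-group means and SDs of daily features, two-stage averaged
#'
#' Patient-level averages are taken first and group statistics are computed
#' over those patient averages, so patients contributing more days are not
#' over-weighted.
#'
#' @param summaries Day-summary data.frame (valid days only are used).
#' @param labels Phenotype labels from [classify_cohort()] (columns
#'   `patient_id`, `label`).
#' @param valid_only Restrict to valid wear days (default `TRUE`).
#' @return Data.frame `measure, group, mean, sd, n_patients`.
#' @export
cohort_daily_table <- function(summaries, labels, valid_only = TRUE) {
  if (valid_only) {
    summaries <- summaries[!is.na(summaries$is_valid_day) & summaries$is_valid_day, ,
                           drop = FALSE]
  }
  summaries <- merge(summaries, labels[, c("patient_id", "label")],
                     by = "patient_id")
  groups <- unique(labels$label)
  if (any(!table(factor(summaries$label, levels = groups)) > 0)) {
    stop("empty group: every group needs at least one patient with valid days")
  }
  feats <- setdiff(names(summaries)[vapply(summaries, is.numeric, logical(1))],
                   "valid_minutes")
  out <- list()
  for (f in feats) {
    pt <- stats::aggregate(summaries[[f]],
                           by = list(patient_id = summaries$patient_id,
                                     label = summaries$label),
                           FUN = function(v) mean(v, na.rm = TRUE))
    pt <- pt[is.finite(pt$x), , drop = FALSE]
    for (g in groups) {
      v <- pt$x[pt$label == g]
      out[[length(out) + 1]] <- data.frame(
        measure = f, group = g, mean = mean(v),
        sd = stats::sd(v), n_patients = length(v),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
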