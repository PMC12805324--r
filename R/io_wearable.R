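#' Minute-file dialect description
#'
#' Describes how a minute-level wearable CSV export maps onto the columns the
#' pipeline needs. The defaults match a Fitabase-style joined export with one
#' row per patient-minute and columns `Id, ActivityMinute, HeartRate, Steps,
#' METs, Intensity`. Fitabase ships METs multiplied by 10; `mets_divisor`
#' undoes that scaling on read.
#'
#' @param col_id,col_time,col_hr,col_steps,col_mets,col_intensity Column
#'   names in the file. `col_hr`, `col_steps`, `col_mets` and `col_intensity`
#'   may be `NA` if the signal is absent from the file.
#' @param time_format `strptime()` format for the minute timestamp.
#' @param mets_divisor Divisor applied to the raw METs column (Fitabase
#'   convention: stored values are METs x 10, so the default is 10).
#' @return A list of class `minute_dialect`.
#' @examples
#' minute_dialect(time_format = "%m/%d/%Y %I:%M:%S %p")
#' @export
minute_dialect <- function(col_id = "Id",
                           col_time = "ActivityMinute",
                           col_hr = "HeartRate",
                           col_steps = "Steps",
                           col_mets = "METs",
                           col_intensity = "Intensity",
                           time_format = "%Y-%m-%d %H:%M:%S",
                           mets_divisor = 10) {
  stopifnot(is.character(col_id), is.character(col_time))
  if (!is.numeric(mets_divisor) || mets_divisor <= 0) {
    stop("mets_divisor must be a positive number")
  }
  structure(list(col_id = col_id, col_time = col_time, col_hr = col_hr,
                 col_steps = col_steps, col_mets = col_mets,
                 col_intensity = col_intensity, time_format = time_format,
                 mets_divisor = mets_divisor),
            class = "minute_dialect")
}

#' Read a minute-level wearable CSV
#'
#' Reads one joined minute-level export into the pipeline's canonical minute
#' table: one row per patient-minute with columns `patient_id`, `timestamp`
#' (local civil time, minute resolution), `hr`, `steps`, `mets`, `intensity`.
#' Records are returned sorted by `(patient_id, timestamp)`.
#'
#' Missing heart rate is encoded as `NA`, never 0. Timestamps must be
#' minute-aligned and unique within a patient.
#'
#' @param path Path to the CSV file.
#' @param dialect A [minute_dialect()] describing the file layout.
#' @return A data.frame of minute records.
#' @export
read_minute_csv <- function(path, dialect = minute_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(dialect$col_id, dialect$col_time)) {
    if (!col %in% names(raw)) {
      stop("format error: required column '", col, "' not found in ", path)
    }
  }
  n <- nrow(raw)
  get_col <- function(col) {
    if (is.na(col) || !col %in% names(raw)) rep(NA_real_, n) else as.numeric(raw[[col]])
  }
  ts <- as.POSIXct(strptime(as.character(raw[[dialect$col_time]]),
                            format = dialect$time_format, tz = "UTC"))
  if (n > 0 && anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop("unparseable datetime '", raw[[dialect$col_time]][bad],
         "' at data row ", bad, " of ", path)
  }
  out <- data.frame(
    patient_id = as.character(raw[[dialect$col_id]]),
    timestamp = ts,
    hr = get_col(dialect$col_hr),
    steps = get_col(dialect$col_steps),
    mets = get_col(dialect$col_mets) / dialect$mets_divisor,
    intensity = get_col(dialect$col_intensity),
    stringsAsFactors = FALSE
  )
  if (n == 0) return(out)
  validate_minutes(out)
  out <- out[order(out$patient_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# shared invariants for a minute table (any source)
validate_minutes <- function(x) {
  if (any(as.integer(format(x$timestamp, "%S")) != 0)) {
    stop("timestamps must be minute-aligned (seconds = 0)")
  }
  dup <- duplicated(x[, c("patient_id", "timestamp")])
  if (any(dup)) {
    stop("duplicate timestamp for patient ", x$patient_id[dup][1],
         " at ", format(x$timestamp[dup][1]))
  }
  st <- x$steps[!is.na(x$steps)]
  if (any(st < 0) || any(st != floor(st))) {
    stop("steps must be non-negative integers")
  }
  iv <- x$intensity[!is.na(x$intensity)]
  if (any(!iv %in% 0:3)) stop("intensity codes must be in {0,1,2,3}")
  mv <- x$mets[!is.na(x$mets)]
  if (any(mv < 0)) stop("METs must be >= 0")
  invisible(x)
}

#' Read separate per-signal Fitabase-style minute files and join on timestamp
#'
#' Fitabase exports one file per signal (heart rate, steps, METs,
#' intensities). This reads each file that is supplied and outer-joins them
#' on `(patient_id, timestamp)`; minutes present in some signals but not
#' others get `NA` for the absent signals.
#'
#' @param hr_path,steps_path,mets_path,intensity_path Paths to the per-signal
#'   CSVs (any may be `NULL`). Each file needs the id/time columns of
#'   `dialect` plus a single value column named as in `dialect`.
#' @param dialect A [minute_dialect()].
#' @return A joined minute data.frame as from [read_minute_csv()].
#' @export
read_fitabase_signals <- function(hr_path = NULL, steps_path = NULL,
                                  mets_path = NULL, intensity_path = NULL,
                                  dialect = minute_dialect()) {
  read_one <- function(path, col, keep) {
    if (is.null(path)) return(NULL)
    d <- dialect
    d$col_hr <- if (keep == "hr") col else NA
    d$col_steps <- if (keep == "steps") col else NA
    d$col_mets <- if (keep == "mets") col else NA
    d$col_intensity <- if (keep == "intensity") col else NA
    x <- read_minute_csv(path, d)
    x[, c("patient_id", "timestamp", keep)]
  }
  parts <- list(
    read_one(hr_path, dialect$col_hr, "hr"),
    read_one(steps_path, dialect$col_steps, "steps"),
    read_one(mets_path, dialect$col_mets, "mets"),
    read_one(intensity_path, dialect$col_intensity, "intensity")
  )
  parts <- Filter(Negate(is.null), parts)
  if (length(parts) == 0) stop("no signal files supplied")
  out <- Reduce(function(a, b) merge(a, b, by = c("patient_id", "timestamp"),
                                     all = TRUE), parts)
  for (col in c("hr", "steps", "mets", "intensity")) {
    if (!col %in% names(out)) out[[col]] <- NA_real_
  }
  out <- out[order(out$patient_id, out$timestamp),
             c("patient_id", "timestamp", "hr", "steps", "mets", "intensity")]
  rownames(out) <- NULL
  out
}

#' Read a daily sleep-session CSV
#'
#' Expects columns `Id, BedStart, BedEnd, MinutesAsleep, MinutesInBed` with
#' ISO datetimes. Sessions violating `minutes_asleep <= minutes_in_bed` or
#' `bed_start < bed_end` are rejected.
#'
#' @param path Path to the CSV.
#' @return A data.frame with columns `patient_id`, `bed_start`, `bed_end`,
#'   `minutes_asleep`, `minutes_in_bed`, `date` (calendar day of `bed_start`).
#' @export
read_sleep_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("Id", "BedStart", "BedEnd", "MinutesAsleep", "MinutesInBed")
  for (col in need) {
    if (!col %in% names(raw)) stop("format error: required column '", col, "' not found")
  }
  out <- data.frame(
    patient_id = as.character(raw$Id),
    bed_start = as.POSIXct(raw$BedStart, tz = "UTC"),
    bed_end = as.POSIXct(raw$BedEnd, tz = "UTC"),
    minutes_asleep = as.numeric(raw$MinutesAsleep),
    minutes_in_bed = as.numeric(raw$MinutesInBed),
    stringsAsFactors = FALSE
  )
  if (nrow(out) > 0) {
    if (any(out$minutes_asleep > out$minutes_in_bed)) {
      stop("minutes_asleep exceeds minutes_in_bed")
    }
    if (any(out$bed_start >= out$bed_end)) stop("bed_start must precede bed_end")
  }
  out$date <- as.Date(out$bed_start, tz = "UTC")
  out[order(out$patient_id, out$bed_start), , drop = FALSE]
}

# measures with hard (validated) and soft (flagged) ranges
pro_hard_ranges <- function() {
  list(phq2 = c(0, 6), gad7 = c(0, 21), pem = c(0, 1))
}

pro_symptoms <- function() {
  c("fatigue", "muscle_pain", "joint_pain", "unrefreshing_sleep",
    "sleep_problems", "memory", "concentration", "dizziness")
}

#' Read a long- or wide-format PRO table
#'
#' Long layout: columns `patient_id, wave, measure, value`. Wide layout: one
#' row per patient-wave, columns `patient_id, wave, <measure...>`. Waves must
#' be `baseline`, `m3` or `m6`. Instrument totals with documented hard ranges
#' (PHQ-2 0-6, GAD-7 0-21, symptom frequency/intensity 0-4) outside those
#' ranges raise a validation error; PROMIS T-scores outside the conventional
#' 20-80 band are flagged in an `out_of_range` column, never clamped.
#'
#' @param path Path to the CSV.
#' @param layout `"long"` or `"wide"`.
#' @return A long data.frame `patient_id, wave, measure, value, out_of_range`.
#' @export
read_pro_table <- function(path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (layout == "long") {
    need <- c("patient_id", "wave", "measure", "value")
    for (col in need) {
      if (!col %in% names(raw)) stop("format error: required column '", col, "' not found")
    }
    out <- raw[, need]
  } else {
    need <- c("patient_id", "wave")
    for (col in need) {
      if (!col %in% names(raw)) stop("format error: required column '", col, "' not found")
    }
    measures <- setdiff(names(raw), need)
    out <- data.frame(
      patient_id = rep(raw$patient_id, times = length(measures)),
      wave = rep(raw$wave, times = length(measures)),
      measure = rep(measures, each = nrow(raw)),
      value = unlist(lapply(measures, function(m) as.numeric(raw[[m]])),
                     use.names = FALSE),
      stringsAsFactors = FALSE
    )
    out <- out[!is.na(out$value), , drop = FALSE]
  }
  out$patient_id <- as.character(out$patient_id)
  out$value <- as.numeric(out$value)
  bad_wave <- !out$wave %in% c("baseline", "m3", "m6")
  if (any(bad_wave)) {
    stop("unknown wave '", out$wave[bad_wave][1],
         "'; waves must be baseline, m3 or m6")
  }
  validate_pro_long(out)
}

validate_pro_long <- function(out) {
  hard <- pro_hard_ranges()
  for (m in names(hard)) {
    v <- out$value[out$measure == m]
    if (length(v) && any(v < hard[[m]][1] | v > hard[[m]][2], na.rm = TRUE)) {
      stop("validation error: ", m, " total outside ",
           hard[[m]][1], "-", hard[[m]][2])
    }
  }
  fi <- grepl("^sym_.*_(freq|int)$", out$measure)
  if (any(fi)) {
    v <- out$value[fi]
    if (any(v < 0 | v > 4 | v != floor(v), na.rm = TRUE)) {
      stop("validation error: symptom frequency/intensity ratings must be integers in 0-4")
    }
  }
  sev <- grepl("_severity$", out$measure)
  if (any(sev)) {
    v <- out$value[sev]
    if (any(v < 0 | v > 16, na.rm = TRUE)) {
      stop("validation error: severity scores must be in 0-16")
    }
  }
  tsc <- grepl("_t$", out$measure)
  out$out_of_range <- FALSE
  out$out_of_range[tsc] <- !is.na(out$value[tsc]) &
    (out$value[tsc] < 20 | out$value[tsc] > 80)
  if (any(out$out_of_range)) {
    warning(sum(out$out_of_range), " T-score(s) outside the 20-80 band flagged")
  }
  dup <- duplicated(out[, c("patient_id", "wave", "measure")])
  if (any(dup)) stop("duplicate patient-wave-measure rows in PRO table")
  out <- out[order(out$patient_id, out$wave, out$measure), , drop = FALSE]
  rownames(out) <- NULL
  out
}

day_summary_columns <- function() {
  c("patient_id", "date", "valid_minutes", "is_valid_day", "sedentary_frac",
    "light_minutes", "mvpa_minutes", "steps", "resting_hr", "max_hr",
    "bedtime_h", "getup_h", "hours_asleep", "sleep_efficiency")
}

#' Write day summaries to CSV
#'
#' Writes the documented column order; floats are rounded to 6 decimals so a
#' write/read round trip reproduces integers bit-exact and floats to 6
#' decimals. An empty input yields a header-only file.
#'
#' @param summaries Day-summary data.frame from [summarize_days()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_day_summaries <- function(summaries, path) {
  cols <- day_summary_columns()
  missing_cols <- setdiff(cols, names(summaries))
  if (length(missing_cols)) {
    stop("day summaries lack columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- summaries[, cols, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) round(v, 6))
  out$date <- as.character(out$date)
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = ""),
    error = function(e) stop("I/O error writing ", path, ": ", conditionMessage(e))
  )
  invisible(path)
}

#' Read day summaries written by [write_day_summaries()]
#' @param path Path to the CSV.
#' @return A day-summary data.frame.
#' @export
read_day_summaries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(day_summary_columns(), names(out))
  if (length(missing_cols)) {
    stop("format error: required column '", missing_cols[1], "' not found")
  }
  out$patient_id <- as.character(out$patient_id)
  out$date <- as.Date(out$date)
  out$is_valid_day <- as.logical(out$is_valid_day)
  out
}
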