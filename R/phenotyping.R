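#' Convert a weekly MVPA guideline to a daily threshold
#'
#' The WHO guideline of 150 MVPA minutes per week becomes a daily threshold
#' of 150/7 = 21.4 minutes, rounded half-up to one decimal.
#'
#' @param weekly_minutes Weekly MVPA minutes (> 0).
#' @return Daily threshold in minutes, one decimal.
#' @examples
#' weekly_to_daily_threshold(150) # 21.4
#' @export
weekly_to_daily_threshold <- function(weekly_minutes) {
  if (!is.numeric(weekly_minutes) || any(weekly_minutes <= 0)) {
    stop("weekly_minutes must be positive")
  }
  floor(weekly_minutes / 7 * 10 + 0.5) / 10
}

#' Phenotyping configuration
#'
#' @param weekly_guideline_minutes Weekly MVPA guideline (default the WHO 150
#'   minutes); the daily threshold is derived via
#'   [weekly_to_daily_threshold()].
#' @param min_valid_days Minimum valid wear days a patient needs to be
#'   classified (default 7, the valid-wear-patient rule).
#' @param inclusive "Reached the threshold" means `>=` (default). Switchable
#'   to strict `>` for sensitivity analysis.
#' @return A list of class `phenotype_config`.
#' @export
phenotype_config <- function(weekly_guideline_minutes = 150,
                             min_valid_days = 7, inclusive = TRUE) {
  structure(list(
    threshold = weekly_to_daily_threshold(weekly_guideline_minutes),
    min_valid_days = min_valid_days, inclusive = inclusive),
    class = "phenotype_config")
}

label_from_mean <- function(mean_mvpa, threshold, inclusive) {
  hit <- if (inclusive) mean_mvpa >= threshold else mean_mvpa > threshold
  ifelse(hit, "active", "inactive")
}

#' Classify patients as MVPA-active or MVPA-inactive
#'
#' Averages daily MVPA minutes over each patient's valid wear days inside
#' the observation window (baseline to the 6-month PRO date when windows are
#' supplied) and labels the patient active when the average reaches the
#' daily threshold.
#'
#' @param summaries Day-summary data.frame.
#' @param windows Optional data.frame `patient_id, start, end` (Dates)
#'   restricting which days count; days outside a patient's window are
#'   ignored. Patients without a window row use all their days.
#' @param config A [phenotype_config()].
#' @return Data.frame `patient_id, mean_daily_mvpa, label, window_start,
#'   window_end, threshold_used, n_valid_days`, one row per classified
#'   patient. Patients with fewer than `min_valid_days` valid days are
#'   excluded and listed in `attr(, "excluded")` with the reason.
#' @export
classify_cohort <- function(summaries, windows = NULL,
                            config = phenotype_config()) {
  s <- summaries[!is.na(summaries$is_valid_day) & summaries$is_valid_day, ,
                 drop = FALSE]
  if (!is.null(windows)) {
    idx <- match(s$patient_id, windows$patient_id)
    keep <- is.na(idx) |
      (s$date >= windows$start[idx] & s$date <= windows$end[idx])
    keep[is.na(keep)] <- TRUE
    s <- s[keep, , drop = FALSE]
  }
  pts <- unique(summaries$patient_id)
  rows <- list(); excluded <- list()
  for (pid in pts) {
    sp <- s[s$patient_id == pid, , drop = FALSE]
    nd <- nrow(sp)
    win <- if (!is.null(windows) && pid %in% windows$patient_id) {
      windows[match(pid, windows$patient_id), c("start", "end")]
    } else if (nd > 0) {
      data.frame(start = min(sp$date), end = max(sp$date))
    } else data.frame(start = as.Date(NA), end = as.Date(NA))
    if (nd < config$min_valid_days) {
      excluded[[length(excluded) + 1]] <- data.frame(
        patient_id = pid, n_valid_days = nd,
        reason = sprintf("fewer than %d valid wear days", config$min_valid_days),
        stringsAsFactors = FALSE)
      next
    }
    mn <- mean(sp$mvpa_minutes)
    rows[[length(rows) + 1]] <- data.frame(
      patient_id = pid, mean_daily_mvpa = mn,
      label = label_from_mean(mn, config$threshold, config$inclusive),
      window_start = win$start, window_end = win$end,
      threshold_used = config$threshold, n_valid_days = nd,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(0), mean_daily_mvpa = numeric(0),
               label = character(0), window_start = as.Date(character(0)),
               window_end = as.Date(character(0)), threshold_used = numeric(0),
               n_valid_days = integer(0))
  if (length(excluded)) {
    excl <- do.call(rbind, excluded)
    message(nrow(excl), " patient(s) excluded from phenotyping: ",
            paste(excl$patient_id, collapse = ", "))
    attr(out, "excluded") <- excl
  }
  out
}

#' Classify a single patient
#' @inheritParams classify_cohort
#' @param day_summaries One patient's day summaries.
#' @return One-row label data.frame (see [classify_cohort()]); errors if the
#'   patient has too few valid days.
#' @export
classify_patient <- function(day_summaries, windows = NULL,
                             config = phenotype_config()) {
  out <- classify_cohort(day_summaries, windows, config)
  if (nrow(out) == 0) {
    stop("patient excluded: fewer than ", config$min_valid_days,
         " valid wear days")
  }
  out
}

#' Perturb phenotype labels for sensitivity analysis
#'
#' Produces deterministic alternative labelings with a provenance record of
#' the perturbation stored in `attr(, "perturbation")`.
#'
#' Modes:
#' \describe{
#'   \item{`threshold_shift`}{rescale the threshold by `delta_pct` percent
#'     and relabel from the stored patient means.}
#'   \item{`swap_near_cutoff`}{flip the `k` patients whose mean daily MVPA
#'     lies closest to the threshold.}
#'   \item{`min_days`}{drop patients with fewer than `m` valid days.}
#'   \item{`window`}{recompute means over each patient's first `days` valid
#'     days (requires `summaries`).}
#' }
#'
#' @param labels Labels from [classify_cohort()].
#' @param mode One of `"threshold_shift"`, `"swap_near_cutoff"`,
#'   `"min_days"`, `"window"`.
#' @param delta_pct,k,m,days Mode parameters.
#' @param summaries Day summaries, needed for `mode = "window"`.
#' @param config A [phenotype_config()] (used for re-labeling rules).
#' @return A perturbed label data.frame.
#' @export
perturb_labels <- function(labels, mode, delta_pct = 0, k = 2, m = 7,
                           days = NULL, summaries = NULL,
                           config = phenotype_config()) {
  out <- labels
  prov <- list(mode = mode)
  if (mode == "threshold_shift") {
    thr <- labels$threshold_used * (1 + delta_pct / 100)
    out$threshold_used <- thr
    out$label <- label_from_mean(out$mean_daily_mvpa, thr, config$inclusive)
    prov$delta_pct <- delta_pct
  } else if (mode == "swap_near_cutoff") {
    stopifnot(k >= 0)
    ord <- order(abs(labels$mean_daily_mvpa - labels$threshold_used))
    flip <- ord[seq_len(min(k, nrow(labels)))]
    out$label[flip] <- ifelse(out$label[flip] == "active", "inactive", "active")
    prov$k <- k
    prov$flipped <- labels$patient_id[flip]
  } else if (mode == "min_days") {
    out <- out[out$n_valid_days >= m, , drop = FALSE]
    prov$min_days <- m
  } else if (mode == "window") {
    if (is.null(summaries) || is.null(days)) {
      stop("mode 'window' needs `summaries` and `days`")
    }
    s <- summaries[!is.na(summaries$is_valid_day) & summaries$is_valid_day, ]
    s <- s[order(s$patient_id, s$date), ]
    rows <- lapply(split(s, s$patient_id), function(sp) {
      sp <- utils::head(sp, days)
      data.frame(patient_id = sp$patient_id[1],
                 mean_daily_mvpa = mean(sp$mvpa_minutes),
                 n_valid_days = nrow(sp), stringsAsFactors = FALSE)
    })
    nw <- do.call(rbind, rows)
    out <- merge(labels[, setdiff(names(labels),
                                  c("mean_daily_mvpa", "n_valid_days", "label"))],
                 nw, by = "patient_id")
    out <- out[out$n_valid_days >= config$min_valid_days, , drop = FALSE]
    out$label <- label_from_mean(out$mean_daily_mvpa, out$threshold_used,
                                 config$inclusive)
    prov$window_days <- days
  } else {
    stop("unknown perturbation mode: ", mode)
  }
  rownames(out) <- NULL
  attr(out, "perturbation") <- prov
  out
}
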