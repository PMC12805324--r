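#' CDC-style symptom severity composite
#'
#' The severity score of a symptom combines how often it occurs and how
#' intense it is: the product of the frequency and intensity ratings, each on
#' a 0-4 ordinal scale, giving a composite in 0-16. An absent symptom scores
#' 0 (both ratings 0).
#'
#' @param frequency,intensity Integer ratings in 0-4 (vectorised).
#' @return Integer severity scores in 0-16.
#' @examples
#' severity_score(4, 4) # 16
#' severity_score(2, 3) # 6
#' @export
severity_score <- function(frequency, intensity) {
  ok <- function(v) is.numeric(v) & !is.na(v) & v >= 0 & v <= 4 & v == floor(v)
  if (!all(ok(frequency)) || !all(ok(intensity))) {
    stop("validation error: frequency and intensity must be integers in 0-4")
  }
  as.integer(frequency * intensity)
}

check_items <- function(items, n, lo, hi, name) {
  if (length(items) != n) {
    stop("validation error: ", name, " needs exactly ", n, " items")
  }
  if (anyNA(items)) return(NA_integer_)  # no prorating: any missing item voids the total
  if (any(items < lo | items > hi | items != floor(items))) {
    stop("validation error: ", name, " items must be integers in ", lo, "-", hi)
  }
  as.integer(sum(items))
}

#' Instrument totals from item responses
#'
#' Simple sums, with no prorating: any missing item makes the total `NA`.
#' PHQ-2 has 2 items scored 0-3 (total 0-6); GAD-7 has 7 items scored 0-3
#' (total 0-21); each PROMIS-29 domain has 4 items scored 1-5 (raw 4-20).
#'
#' @param items Numeric vector of item responses.
#' @return Integer total or `NA`.
#' @name instrument-totals
NULL

#' @rdname instrument-totals
#' @export
score_phq2 <- function(items) check_items(items, 2, 0, 3, "PHQ-2")

#' @rdname instrument-totals
#' @export
score_gad7 <- function(items) check_items(items, 7, 0, 3, "GAD-7")

#' @rdname instrument-totals
#' @export
score_promis_domain <- function(items) check_items(items, 4, 1, 5, "PROMIS domain")

#' PHQ-2 depression screen
#'
#' A PHQ-2 total of 3 or greater indicates that major depressive disorder is
#' likely.
#'
#' @param total PHQ-2 total (0-6).
#' @return Logical flag (`NA` for missing totals).
#' @export
phq2_depression_flag <- function(total) {
  if (any(!is.na(total) & (total < 0 | total > 6))) {
    stop("validation error: PHQ-2 total outside 0-6")
  }
  total >= 3
}

#' Severity category from a PROMIS T-score
#'
#' Maps a T-score to acceptable/mild, moderate or significant concern using
#' the conventional 1-SD/2-SD bands. For higher-worse domains (depression,
#' anxiety, fatigue, sleep disturbance, pain interference, dyspnea):
#' T < 60 acceptable/mild, 60 <= T < 70 moderate, T >= 70 significant. For
#' lower-worse domains (physical function, social roles, cognition) the
#' bands mirror at 40/30: T > 40 acceptable/mild, 30 < T <= 40 moderate,
#' T <= 30 significant. Cutoffs are configurable.
#'
#' @param t_score Numeric T-scores (vectorised).
#' @param direction `"higher_worse"` or `"lower_worse"`.
#' @param cutoffs Two increasing cutoffs on the higher-worse scale
#'   (default `c(60, 70)`); lower-worse bands use their mirror about 50.
#' @return Character vector: `"acceptable_mild"`, `"moderate"`,
#'   `"significant"`.
#' @export
severity_category <- function(t_score, direction = c("higher_worse", "lower_worse"),
                              cutoffs = c(60, 70)) {
  direction <- match.arg(direction)
  stopifnot(length(cutoffs) == 2, cutoffs[1] < cutoffs[2])
  if (direction == "lower_worse") {
    lo <- 100 - cutoffs  # mirror about the population mean of 50
    ifelse(t_score <= lo[2], "significant",
           ifelse(t_score <= lo[1], "moderate", "acceptable_mild"))
  } else {
    ifelse(t_score >= cutoffs[2], "significant",
           ifelse(t_score >= cutoffs[1], "moderate", "acceptable_mild"))
  }
}

#' Direction of each PROMIS domain used here
#'
#' On physical function, social roles and cognition a lower score indicates
#' more severe problems; on all other domains a higher score does.
#'
#' @param measure Measure names such as `"fatigue_t"`.
#' @return `"higher_worse"` or `"lower_worse"` per measure; errors on an
#'   unknown domain.
#' @export
promis_direction <- function(measure) {
  lower <- c("physical_function", "social_roles", "cognition")
  base <- sub("_(t|raw)$", "", measure)
  known <- c(lower, "depression", "anxiety", "fatigue", "sleep_disturbance",
             "pain_interference", "dyspnea")
  if (any(!base %in% known)) {
    stop("unknown domain: ", paste(unique(base[!base %in% known]), collapse = ", "))
  }
  ifelse(base %in% lower, "lower_worse", "higher_worse")
}

#' Convert PROMIS raw domain scores to T-scores via a user-supplied lookup
#'
#' The package ships no conversion tables (they are licensed scoring-service
#' content); supply a CSV/data.frame with columns `domain, raw, t`.
#'
#' @param raw Raw domain scores.
#' @param domain Domain name (scalar).
#' @param lookup Data.frame `domain, raw, t`.
#' @return T-scores; errors when a raw score has no table entry.
#' @export
apply_tscore_lookup <- function(raw, domain, lookup) {
  stopifnot(all(c("domain", "raw", "t") %in% names(lookup)))
  tab <- lookup[lookup$domain == domain, , drop = FALSE]
  if (nrow(tab) == 0) stop("no lookup rows for domain ", domain)
  idx <- match(raw, tab$raw)
  if (anyNA(idx[!is.na(raw)])) stop("raw score missing from lookup for ", domain)
  tab$t[idx]
}

#' Derive per-symptom severity scores in a long PRO table
#'
#' For every `sym_<name>_freq` / `sym_<name>_int` pair present at a
#' patient-wave, appends a `sym_<name>_severity` row with the product score.
#'
#' @param pro Long PRO data.frame (`patient_id, wave, measure, value`).
#' @return The table with severity rows appended.
#' @export
derive_severity_scores <- function(pro) {
  fr <- pro[grepl("^sym_.*_freq$", pro$measure), , drop = FALSE]
  if (nrow(fr) == 0) return(pro)
  fr$sym <- sub("_freq$", "", fr$measure)
  it <- pro[grepl("^sym_.*_int$", pro$measure), , drop = FALSE]
  it$sym <- sub("_int$", "", it$measure)
  mg <- merge(fr[, c("patient_id", "wave", "sym", "value")],
              it[, c("patient_id", "wave", "sym", "value")],
              by = c("patient_id", "wave", "sym"),
              suffixes = c("_freq", "_int"))
  if (nrow(mg) == 0) return(pro)
  sev <- data.frame(
    patient_id = mg$patient_id, wave = mg$wave,
    measure = paste0(mg$sym, "_severity"),
    value = as.numeric(severity_score(mg$value_freq, mg$value_int)),
    stringsAsFactors = FALSE
  )
  for (col in setdiff(names(pro), names(sev))) sev[[col]] <- NA
  out <- rbind(pro, sev[, names(pro)])
  out[order(out$patient_id, out$wave, out$measure), , drop = FALSE]
}

#' Within-subject change scores between waves
#'
#' Pairwise deltas (later wave minus baseline) per patient and measure,
#' emitted only when both waves are present — patients missing either wave
#' contribute nothing for that pair.
#'
#' @param pro Long PRO data.frame.
#' @param from Reference wave (default `"baseline"`).
#' @param to Target waves (default `c("m3", "m6")`).
#' @return Data.frame `patient_id, measure, from_wave, to_wave, delta`.
#' @export
change_scores <- function(pro, from = "baseline", to = c("m3", "m6")) {
  base <- pro[pro$wave == from & !is.na(pro$value), , drop = FALSE]
  out <- list()
  for (w in to) {
    tw <- pro[pro$wave == w & !is.na(pro$value), , drop = FALSE]
    mg <- merge(base[, c("patient_id", "measure", "value")],
                tw[, c("patient_id", "measure", "value")],
                by = c("patient_id", "measure"),
                suffixes = c("_from", "_to"))
    if (nrow(mg) == 0) next
    out[[w]] <- data.frame(
      patient_id = mg$patient_id, measure = mg$measure,
      from_wave = from, to_wave = w,
      delta = mg$value_to - mg$value_from,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(patient_id = character(0), measure = character(0),
                      from_wave = character(0), to_wave = character(0),
                      delta = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group-level change-score table
#'
#' Mean (SD) of within-subject changes per measure, target wave and
#' phenotype group — computed only over patients with both waves, so cell
#' sample sizes shrink with missingness.
#'
#' @param changes Output of [change_scores()].
#' @param labels Phenotype labels (`patient_id`, `label`).
#' @return Data.frame `measure, to_wave, group, mean, sd, n`.
#' @export
change_score_table <- function(changes, labels) {
  mg <- merge(changes, labels[, c("patient_id", "label")], by = "patient_id")
  if (nrow(mg) == 0) {
    return(data.frame(measure = character(0), to_wave = character(0),
                      group = character(0), mean = numeric(0),
                      sd = numeric(0), n = integer(0)))
  }
  agg <- stats::aggregate(mg$delta,
                          by = list(measure = mg$measure, to_wave = mg$to_wave,
                                    group = mg$label),
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(agg[, 1:3], mean = agg$x[, "mean"], sd = agg$x[, "sd"],
                    n = as.integer(agg$x[, "n"]))
  out[order(out$measure, out$to_wave, out$group), , drop = FALSE]
}
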