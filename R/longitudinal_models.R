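#' Specify a longitudinal mixed-effects model of a PRO
#'
#' The default model follows the study design: outcome scores at baseline, 3
#' and 6 months regressed on time (coded 0/1/2 in 3-month units so the
#' group-by-time coefficient is "per 3 months"), phenotype group, their
#' interaction and the baseline score, plus a random intercept per patient,
#' fitted by REML. Baseline rows are modelled as outcomes while the baseline
#' score also enters as a covariate; `include_baseline_rows = FALSE` gives
#' the follow-up-only variant used in sensitivity analysis.
#'
#' @param outcome Measure name (matched against a `measure` column when
#'   present).
#' @param time_coding `"linear"` (0/1/2 in 3-month units) or
#'   `"categorical"`.
#' @param baseline_covariate Include the baseline score as a fixed
#'   covariate.
#' @param include_baseline_rows Model baseline-wave rows as outcomes.
#' @param estimation `"REML"` (default) or `"ML"` (required for AIC
#'   comparison across fixed-effect structures).
#' @param scale `"t"` when the outcome is a T-score (enables the
#'   3-T-point meaningful-change annotation) or `"raw"`.
#' @param interaction Include the group-by-time interaction (default `TRUE`;
#'   both main effects always stay in the model).
#' @return A list of class `lme_spec`.
#' @export
lme_spec <- function(outcome, time_coding = c("linear", "categorical"),
                     baseline_covariate = TRUE, include_baseline_rows = TRUE,
                     estimation = c("REML", "ML"), scale = c("t", "raw"),
                     interaction = TRUE) {
  structure(list(outcome = outcome, time_coding = match.arg(time_coding),
                 baseline_covariate = baseline_covariate,
                 include_baseline_rows = include_baseline_rows,
                 estimation = match.arg(estimation), scale = match.arg(scale),
                 interaction = interaction),
            class = "lme_spec")
}

# long input -> model frame with time, group factor (inactive reference so
# coefficients read "active vs inactive"), baseline covariate
build_lme_frame <- function(data, spec) {
  d <- data
  if ("measure" %in% names(d)) d <- d[d$measure == spec$outcome, , drop = FALSE]
  val_col <- if ("value" %in% names(d)) "value" else spec$outcome
  if (!val_col %in% names(d)) stop("outcome column not found: ", spec$outcome)
  d <- d[, c("patient_id", "wave", "group", val_col)]
  names(d)[4] <- "value"
  d <- d[!is.na(d$value), , drop = FALSE]
  if (nrow(d) == 0) stop("all outcome values missing for ", spec$outcome)
  if (length(unique(d$wave)) < 2) stop("need at least 2 waves represented")
  d$time <- match(d$wave, c("baseline", "m3", "m6")) - 1
  if (anyNA(d$time)) stop("waves must be baseline, m3, m6")
  d$group <- factor(d$group, levels = c("inactive", "active"))
  base <- d[d$time == 0, c("patient_id", "value")]
  names(base)[2] <- "baseline"
  d <- merge(d, base, by = "patient_id", all.x = TRUE)
  if (spec$baseline_covariate) d <- d[!is.na(d$baseline), , drop = FALSE]
  if (!spec$include_baseline_rows) d <- d[d$time > 0, , drop = FALSE]
  if (spec$time_coding == "categorical") {
    d$time_f <- factor(d$time)
  }
  d
}

lme_formula <- function(spec) {
  tv <- if (spec$time_coding == "categorical") "time_f" else "time"
  op <- if (isFALSE(spec$interaction)) " + " else " * "
  rhs <- paste0(tv, op, "group")
  if (spec$baseline_covariate) rhs <- paste(rhs, "+ baseline")
  stats::as.formula(paste("value ~", rhs, "+ (1 | patient_id)"))
}

#' Fit the longitudinal mixed-effects model
#'
#' REML (or ML) fit with a patient random intercept via `lmerTest`;
#' p-values use Satterthwaite denominator degrees of freedom and confidence
#' intervals are Wald with the same df. Non-convergence and singular
#' random-effect fits are flagged, never silently swallowed. For T-score
#' outcomes the group-by-time estimate is annotated when its magnitude
#' reaches the 3-T-point meaningful-change threshold.
#'
#' @param data Long table with columns `patient_id, wave, group` and either
#'   `measure`/`value` columns or a column named after the outcome.
#' @param spec An [lme_spec()].
#' @return A list of class `lme_fit`: `coefficients` (estimate, se, df, p,
#'   95% CI), `interaction` (the group-by-time row), `AIC`, `n_obs`,
#'   `n_patients`, `converged`, `singular`, `residuals`, `fitted`,
#'   `meaningful_change`.
#' @export
fit_lme <- function(data, spec) {
  d <- build_lme_frame(data, spec)
  if (stats::var(d$value) == 0) {
    # degenerate: constant outcome; slope/interaction are exactly 0
    co <- data.frame(term = c("(Intercept)", "time", "groupactive",
                              "time:groupactive"),
                     estimate = c(d$value[1], 0, 0, 0), se = NA_real_,
                     df = NA_real_, p = NA_real_,
                     ci_lo = NA_real_, ci_hi = NA_real_)
    out <- list(spec = spec, coefficients = co,
                interaction = co[co$term == "time:groupactive", ],
                AIC = -Inf, n_obs = nrow(d),
                n_patients = length(unique(d$patient_id)),
                converged = TRUE, singular = TRUE, degenerate = TRUE,
                residuals = rep(0, nrow(d)), fitted = d$value,
                meaningful_change = FALSE)
    class(out) <- "lme_fit"
    return(out)
  }
  fml <- lme_formula(spec)
  fit <- lmerTest::lmer(fml, data = d, REML = spec$estimation == "REML",
                        control = lme4::lmerControl(
                          check.conv.singular = "ignore",
                          calc.derivs = FALSE))
  sm <- summary(fit)$coefficients
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  if (!conv) warning("mixed-model fit did not converge cleanly")
  qs <- stats::qt(0.975, sm[, "df"])
  co <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                   se = sm[, "Std. Error"], df = sm[, "df"],
                   p = sm[, "Pr(>|t|)"],
                   ci_lo = sm[, "Estimate"] - qs * sm[, "Std. Error"],
                   ci_hi = sm[, "Estimate"] + qs * sm[, "Std. Error"],
                   row.names = NULL, stringsAsFactors = FALSE)
  int_terms <- grep(":groupactive$", co$term)
  interaction <- co[int_terms, , drop = FALSE]
  mc <- spec$scale == "t" && nrow(interaction) > 0 &&
    any(abs(interaction$estimate) >= 3)
  out <- list(spec = spec, coefficients = co, interaction = interaction,
              AIC = stats::AIC(fit), n_obs = nrow(d),
              n_patients = length(unique(d$patient_id)),
              converged = conv, singular = lme4::isSingular(fit),
              degenerate = FALSE,
              residuals = stats::residuals(fit), fitted = stats::fitted(fit),
              meaningful_change = mc)
  class(out) <- "lme_fit"
  out
}

#' @export
print.lme_fit <- function(x, ...) {
  cat(sprintf("Mixed-effects fit of %s: %d obs, %d patients, AIC %.1f%s\n",
              x$spec$outcome, x$n_obs, x$n_patients, x$AIC,
              if (x$singular) " (singular random effect)" else ""))
  print(x$coefficients, digits = 3)
  if (isTRUE(x$meaningful_change)) {
    cat("group-by-time estimate reaches the 3 T-point meaningful-change threshold\n")
  }
  invisible(x)
}

#' Rank candidate model specifications by AIC
#'
#' Candidates are refitted by maximum likelihood (AIC across different
#' fixed-effect structures is not comparable under REML) and must use the
#' same observation set.
#'
#' @param specs Named list of [lme_spec()] objects.
#' @param data Long table as for [fit_lme()].
#' @return Data.frame `spec, AIC, dAIC` ranked best-first, with the fits in
#'   `attr(, "fits")`.
#' @export
select_model <- function(specs, data) {
  if (is.null(names(specs))) names(specs) <- paste0("spec", seq_along(specs))
  fits <- lapply(specs, function(sp) {
    sp$estimation <- "ML"
    fit_lme(data, sp)
  })
  ns <- vapply(fits, `[[`, numeric(1), "n_obs")
  if (length(unique(ns)) > 1) {
    stop("candidates use different observation sets (",
         paste(unique(ns), collapse = " vs "), " rows); AICs are not comparable")
  }
  aics <- vapply(fits, `[[`, numeric(1), "AIC")
  ord <- order(aics)
  out <- data.frame(spec = names(specs)[ord], AIC = aics[ord],
                    dAIC = aics[ord] - min(aics), stringsAsFactors = FALSE)
  attr(out, "fits") <- fits
  out
}

#' Residual diagnostics for a mixed-effects fit
#'
#' Shapiro-Wilk on the conditional residuals and the White Lagrange
#' multiplier test of residual variance homogeneity (auxiliary regression of
#' squared residuals on fitted values and their squares; LM = n R-squared
#' against chi-squared with 2 df). Both p-values are reported; no automatic
#' refitting.
#'
#' @param fit An `lme_fit`.
#' @return A list `shapiro_p`, `white_lm_p`, `white_lm_stat`, `degenerate`.
#' @export
diagnose_fit <- function(fit) {
  e <- fit$residuals
  if (length(e) < 3) stop("need at least 3 residuals for diagnostics")
  if (isTRUE(fit$degenerate) || stats::var(e) == 0) {
    return(list(shapiro_p = NA_real_, white_lm_p = NA_real_,
                white_lm_stat = NA_real_, degenerate = TRUE))
  }
  sw <- stats::shapiro.test(if (length(e) > 5000) sample(e, 5000) else e)
  f <- fit$fitted
  aux <- stats::lm(I(e^2) ~ f + I(f^2))
  lm_stat <- length(e) * summary(aux)$r.squared
  list(shapiro_p = sw$p.value,
       white_lm_p = stats::pchisq(lm_stat, 2, lower.tail = FALSE),
       white_lm_stat = lm_stat, degenerate = FALSE)
}

#' Sensitivity-analysis grid around a base mixed-effects fit
#'
#' Refits the base model under named perturbations and reports the
#' group-by-time estimate of each variant together with a sign-stability
#' flag. Supported variant types: `labels` (an alternative phenotype
#' labelling, e.g. from [perturb_labels()]), `categorical_time`,
#' `drop_single_wave_patients`, `no_baseline_rows`,
#' `no_baseline_covariate`.
#'
#' @param data Long table as for [fit_lme()] (its `group` column is
#'   re-derived from variant labels where applicable).
#' @param base_spec The reference [lme_spec()].
#' @param variants Named list; each element is `list(type = ...)` plus
#'   type-specific fields (`labels` for the labels type).
#' @return Data.frame with one row per variant (plus the base row):
#'   `variant, estimate, ci_lo, ci_hi, p, n_patients, sign_stable,
#'   feasible`.
#' @export
sensitivity_grid <- function(data, base_spec, variants) {
  base_fit <- fit_lme(data, base_spec)
  base_est <- base_fit$interaction$estimate[1]
  row_of <- function(name, fit, feasible = TRUE) {
    if (!feasible || nrow(fit$interaction) == 0) {
      return(data.frame(variant = name, estimate = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, p = NA_real_, n_patients = NA_integer_,
                        sign_stable = NA, feasible = feasible,
                        stringsAsFactors = FALSE))
    }
    it <- fit$interaction[1, ]
    data.frame(variant = name, estimate = it$estimate, ci_lo = it$ci_lo,
               ci_hi = it$ci_hi, p = it$p, n_patients = fit$n_patients,
               sign_stable = sign(it$estimate) == sign(base_est),
               feasible = TRUE, stringsAsFactors = FALSE)
  }
  rows <- list(row_of("base", base_fit))
  for (nm in names(variants)) {
    v <- variants[[nm]]
    d <- data; sp <- base_spec
    feasible <- TRUE
    if (v$type == "labels") {
      lb <- v$labels
      idx <- match(d$patient_id, lb$patient_id)
      d$group <- lb$label[idx]
      d <- d[!is.na(d$group), , drop = FALSE]
      if (length(unique(d$group)) < 2) feasible <- FALSE
    } else if (v$type == "categorical_time") {
      sp$time_coding <- "categorical"
    } else if (v$type == "drop_single_wave_patients") {
      dd <- d
      if ("measure" %in% names(dd)) dd <- dd[dd$measure == sp$outcome, ]
      dd <- dd[!is.na(dd$value), ]
      waves_per <- tapply(dd$wave, dd$patient_id,
                          function(w) length(unique(w)))
      keep <- names(waves_per)[waves_per >= 2]
      d <- d[d$patient_id %in% keep, , drop = FALSE]
    } else if (v$type == "no_baseline_rows") {
      sp$include_baseline_rows <- FALSE
    } else if (v$type == "no_baseline_covariate") {
      sp$baseline_covariate <- FALSE
    } else {
      stop("unknown variant type: ", v$type)
    }
    fit <- if (feasible) {
      tryCatch(fit_lme(d, sp), error = function(e) NULL)
    } else NULL
    if (is.null(fit)) feasible <- FALSE
    rows[[length(rows) + 1]] <-
      if (feasible) row_of(nm, fit) else row_of(nm, NULL, feasible = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
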