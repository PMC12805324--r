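#' Run the full cohort pipeline end to end
#'
#' Chains every stage over a synthetic cohort: simulate, validate wear time,
#' extract daily features, phenotype, score PROs, compare groups, fit the
#' longitudinal mixed model and the growth mixture model. Each stage writes
#' its outputs under `out_dir` and a closing manifest records the
#' configuration snapshot, package version, seed, per-file MD5 hashes and
#' the exclusion tallies; re-running with an identical configuration and
#' seed reproduces byte-identical outputs. Any stage failure halts the run
#' with a stage-named error.
#'
#' @param cohort A [cohort_config()] (its `seed` drives the whole run).
#' @param out_dir Output directory.
#' @param validation A [validation_config()].
#' @param features A [features_config()].
#' @param phenotype A [phenotype_config()].
#' @param lme_outcome PRO measure for the mixed-model stage.
#' @param gmm_measure Day-summary feature for the mixture-model stage.
#' @param gmm_k_max Largest latent class count tried.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(cohort, out_dir,
                         validation = validation_config(),
                         features = features_config(),
                         phenotype = phenotype_config(),
                         lme_outcome = "social_roles_t",
                         gmm_measure = "mvpa_minutes",
                         gmm_k_max = 2) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(validation, "validation_config"),
            inherits(features, "features_config"),
            inherits(phenotype, "phenotype_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  stages <- character(0)
  outputs <- character(0)
  add_out <- function(path) outputs <<- c(outputs, path)

  # 1: simulate --------------------------------------------------------------
  paths <- stage("simulate", make_fixture_suite(out_dir, cohort))
  stages <- c(stages, "simulate")
  add_out(paths)

  # 2: validate --------------------------------------------------------------
  val <- stage("validate", {
    minutes <- read_minute_csv(paths["minutes"])
    validate_cohort(minutes, validation)
  })
  flags_path <- file.path(out_dir, "minute_flags.csv")
  fl <- val$minutes
  fl$timestamp <- format(fl$timestamp, "%Y-%m-%d %H:%M:%S")
  utils::write.csv(fl, flags_path, row.names = FALSE, quote = FALSE, na = "")
  verdict_path <- file.path(out_dir, "day_verdicts.csv")
  utils::write.csv(val$days, verdict_path, row.names = FALSE, quote = FALSE)
  tally_path <- file.path(out_dir, "exclusion_tally.json")
  jsonlite::write_json(val$exclusion_tally, tally_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  stages <- c(stages, "validate")
  add_out(c(flags_path, verdict_path, tally_path))

  # 3: features --------------------------------------------------------------
  summaries <- stage("features", {
    sleep <- read_sleep_csv(paths["sleep"])
    summarize_days(val, sleep, config = features)
  })
  days_path <- file.path(out_dir, "day_summaries.csv")
  write_day_summaries(summaries, days_path)
  stages <- c(stages, "features")
  add_out(days_path)

  # 4: phenotype -------------------------------------------------------------
  labels <- stage("phenotype", classify_cohort(summaries, config = phenotype))
  labels_path <- file.path(out_dir, "labels.csv")
  utils::write.csv(labels, labels_path, row.names = FALSE, quote = FALSE)
  stages <- c(stages, "phenotype")
  add_out(labels_path)

  # 5: score -----------------------------------------------------------------
  scored <- stage("score", {
    pro <- read_pro_table(paths["pro"], layout = "long")
    pro <- derive_severity_scores(pro)
    pro$phq2_flag <- NA
    is_phq2 <- pro$measure == "phq2"
    pro$phq2_flag[is_phq2] <- phq2_depression_flag(pro$value[is_phq2])
    pro
  })
  scored_path <- file.path(out_dir, "scored.csv")
  utils::write.csv(scored, scored_path, row.names = FALSE, quote = FALSE, na = "")
  changes <- change_scores(scored)
  changes_path <- file.path(out_dir, "changes.csv")
  utils::write.csv(changes, changes_path, row.names = FALSE, quote = FALSE)
  stages <- c(stages, "score")
  add_out(c(scored_path, changes_path))

  # 6: compare ---------------------------------------------------------------
  comparisons <- stage("compare", {
    if (nrow(labels) < 2 || length(unique(labels$label)) < 2) {
      data.frame(measure = character(0), test = character(0),
                 statistic = numeric(0), p = numeric(0))
    } else {
      tab <- cohort_daily_table(summaries, labels)
      feats <- unique(tab$measure)
      rows <- lapply(feats, function(f) {
        pt <- stats::aggregate(
          summaries[[f]][summaries$is_valid_day],
          by = list(patient_id = summaries$patient_id[summaries$is_valid_day]),
          FUN = mean)
        pt$label <- labels$label[match(pt$patient_id, labels$patient_id)]
        pt <- pt[!is.na(pt$label) & is.finite(pt$x), ]
        if (length(unique(pt$label)) < 2) return(NULL)
        cr <- suppressWarnings(compare_groups(pt$x, pt$label, "continuous"))
        data.frame(measure = f, test = cr$test_used,
                   statistic = cr$statistic, p = cr$p_value)
      })
      do.call(rbind, Filter(Negate(is.null), rows))
    }
  })
  comp_path <- file.path(out_dir, "comparisons.csv")
  utils::write.csv(comparisons, comp_path, row.names = FALSE, quote = FALSE)
  stages <- c(stages, "compare")
  add_out(comp_path)

  # 7: lme -------------------------------------------------------------------
  lme_json <- stage("lme", {
    d <- scored[scored$measure == lme_outcome,
                c("patient_id", "wave", "measure", "value")]
    d$group <- labels$label[match(d$patient_id, labels$patient_id)]
    d <- d[!is.na(d$group), ]
    if (length(unique(d$group)) < 2 || length(unique(d$wave)) < 2) {
      list(skipped = "too few groups or waves for a mixed model")
    } else {
      fit <- fit_lme(d, lme_spec(lme_outcome))
      list(outcome = lme_outcome, coefficients = fit$coefficients,
           AIC = fit$AIC, n_obs = fit$n_obs, n_patients = fit$n_patients,
           singular = fit$singular, converged = fit$converged)
    }
  })
  lme_path <- file.path(out_dir, "lme_fit.json")
  jsonlite::write_json(lme_json, lme_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  stages <- c(stages, "lme")
  add_out(lme_path)

  # 8: gmm -------------------------------------------------------------------
  gmm_json <- stage("gmm", {
    series <- gmm_series(summaries, gmm_measure, valid_only = TRUE)
    series <- series[!is.na(series$value), ]
    counts <- table(series$patient_id)
    series <- series[series$patient_id %in% names(counts)[counts >= 2], ]
    if (length(unique(series$patient_id)) < 2) {
      list(skipped = "too few patients with day series")
    } else {
      sel <- suppressWarnings(
        select_classes(series, gmm_k_max, gmm_spec(seed = cohort$seed)))
      list(measure = gmm_measure, bic_table = sel$table,
           chosen_k = sel$chosen_k,
           classes = sel$fits[[as.character(sel$chosen_k)]]$classes)
    }
  })
  gmm_path <- file.path(out_dir, "gmm_fit.json")
  jsonlite::write_json(gmm_json, gmm_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  stages <- c(stages, "gmm")
  add_out(gmm_path)

  # manifest ------------------------------------------------------------------
  cfg <- cohort
  cfg$start_date <- as.character(cfg$start_date)
  manifest <- list(
    package = "wearcohort",
    version = as.character(utils::packageVersion("wearcohort")),
    seed = cohort$seed,
    stages = stages,
    config = list(cohort = unclass(cfg), validation = unclass(validation),
                  features = unclass(features), phenotype = unclass(phenotype)),
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs))),
    exclusion_tally = val$exclusion_tally
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
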