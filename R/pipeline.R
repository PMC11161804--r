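#' Paradigm-default analysis configuration
#'
#' The standard settings for this paradigm: pre-naming window `[0, 367)`
#' ms, analysis window `[367, 3500)` ms, 20 ms gaze bins, the one-third
#' minimum-looking rule (3133/3 ms), subject retention at half the
#' designed trial count, subject-resampled bootstrap, standardised age in
#' the extended logit model, and the 33 ms timecourse grid over
#' `[-1000, 3500)` ms. The mixed logit random structure follows the
#' design: subject and item intercepts for the nouns experiment, subject
#' only for the honorifics experiment.
#'
#' @param experiment `"NOUNS"` or `"HONORIFICS"`.
#' @param boot_reps bootstrap replicates for score CIs.
#' @param timecourse_reps bootstrap replicates for timecourse interval CIs.
#' @param seed seed for all resampling in the analysis.
#' @return named list of class `analysis_config`.
#' @export
paradigm_defaults <- function(experiment = c("NOUNS", "HONORIFICS"),
                           boot_reps = 10000, timecourse_reps = 1000,
                              seed = 1L) {
  experiment <- match.arg(experiment)
  structure(
    list(
      experiment = experiment,
      prenaming = window_prenaming(),
      analysis = window_analysis(),
      bin_ms = 20,
      timecourse_grid_ms = 33,
      timecourse_range_ms = c(-1000, 3500),
      loess_span = 0.25,
      boot_reps = boot_reps,
      timecourse_reps = timecourse_reps,
      seed = as.integer(seed),
      glmm_random = if (experiment == "NOUNS") "subject_item" else "subject",
      standardize_age = TRUE
    ),
    class = "analysis_config"
  )
}

#' Run the full gaze analysis
#'
#' Executes the pipeline end to end: alignment, trial classification,
#' subject filtering, pair-based difference scores with bootstrap /
#' Wilcoxon / sign-test / Cohen's d / age-correlation inference, the
#' random-intercept LMM of scores, the pre/post-naming binomial mixed
#' logit models (phase-only and phase-by-age) with their likelihood-ratio
#' comparison, and the proportion-looking timecourse. Deterministic given
#' the study and config.
#'
#' @param study a `gaze_study`.
#' @param config an [paradigm_defaults()] configuration.
#' @return list of class `result_bundle`; see the elements written by
#'   [write_bundle()].
#' @export
run_analysis <- function(study, config = paradigm_defaults()) {
  stopifnot(inherits(study, "gaze_study"))
  exclusions <- classify_study(study)
  filt <- filter_subjects(study, exclusions)

  retained <- filt$retained
  keep_trial <- study$trials$trial_id[study$trials$subject_id %in% retained]
  study_kept <- study
  study_kept$subjects <-
    study$subjects[study$subjects$subject_id %in% retained, , drop = FALSE]
  study_kept$trials <-
    study$trials[study$trials$subject_id %in% retained, , drop = FALSE]
  study_kept$looks <-
    study$looks[study$looks$subject_id %in% retained, , drop = FALSE]
  excl_kept <- exclusions[exclusions$trial_id %in% keep_trial, , drop = FALSE]

  scores <- pair_scores(study_kept, excl_kept, window = config$analysis)
  table <- aggregate_scores(scores)

  item_vals <- table$item_means$mean_score
  subj_vals <- table$subject_means$mean_score
  boots <- list(
    grand_item_mean = subject_level_bootstrap(
      table$scores, grand_item_mean_stat, config$boot_reps, config$seed
    ),
    grand_subject_mean = percentile_bootstrap_ci(
      subj_vals, n_reps = config$boot_reps, seed = config$seed + 1L,
      resampling_unit = "SUBJECT"
    ),
    item_means = lapply(
      setNames(table$item_means$word_pair_id, table$item_means$word_pair_id),
      function(wp) {
        vals <- table$scores$score[table$scores$word_pair_id == wp]
        if (length(vals) < 2) return(NULL)
        percentile_bootstrap_ci(vals, n_reps = config$boot_reps,
                                seed = config$seed + 2L,
                                resampling_unit = "SUBJECT")
      }
    )
  )
  tests <- list(
    item_wilcoxon = wilcoxon_signed_rank(item_vals),
    item_sign = exact_sign_test(sum(item_vals > 0), sum(item_vals != 0)),
    item_cohens_d = one_sample_cohens_d(item_vals),
    subject_wilcoxon = wilcoxon_signed_rank(subj_vals),
    subject_sign = exact_sign_test(sum(subj_vals > 0), sum(subj_vals != 0)),
    subject_cohens_d = one_sample_cohens_d(subj_vals)
  )
  ages <- study_kept$subjects$age_months[
    match(table$subject_means$subject_id, study_kept$subjects$subject_id)
  ]
  tests$age_kendall <- tryCatch(kendall_tau(subj_vals, ages),
                                error = function(e) NULL)

  lmm <- fit_intercept_lmm(table$scores)

  counts <- phase_bin_counts(study_kept, excl_kept, bin_ms = config$bin_ms,
                             prenaming = config$prenaming,
                             analysis = config$analysis)
  glmm_phase <- fit_phase_glmm(counts, random = config$glmm_random)
  glmm_age <- fit_phase_glmm(counts, random = config$glmm_random, age = TRUE,
                             standardize_age = config$standardize_age)
  glmm_comparison <- compare_models(glmm_phase, glmm_age)

  curve <- proportion_curve(
    study_kept, excl_kept, grid_ms = config$timecourse_grid_ms,
    range_ms = config$timecourse_range_ms,
    n_reps = config$timecourse_reps, seed = config$seed + 3L
  )
  curve <- smooth_curve(curve, span = config$loess_span)

  structure(
    list(
      config = config,
      exclusions = exclusions,
      subject_filter = filt,
      score_table = table,
      bootstrap = boots,
      tests = tests,
      lmm = lmm,
      glmm_phase = glmm_phase,
      glmm_age = glmm_age,
      glmm_comparison = glmm_comparison,
      timecourse = curve,
      run_info = list(
        seed = config$seed,
        n_subjects_in = nrow(study$subjects),
        n_subjects_retained = length(retained),
        n_trials_in = nrow(study$trials),
        n_trials_excluded = sum(exclusions$excluded),
        package_version = as.character(utils::packageVersion("gazelex")),
        timestamp = format(Sys.time(), tz = "UTC")
      )
    ),
    class = "result_bundle"
  )
}

# Grand item mean recomputed from a subject-resampled score table.
grand_item_mean_stat <- function(scores) {
  item <- tapply(scores$score, scores$word_pair_id, mean)
  mean(item)
}

# Bootstrap a score-table statistic by resampling subjects with
# replacement (a drawn subject contributes all their scores each time).
subject_level_bootstrap <- function(scores, statistic, n_reps, seed,
                                    level = 0.95) {
  ids <- unique(scores$subject_id)
  split_rows <- split(seq_len(nrow(scores)), scores$subject_id)
  est <- statistic(scores)
  stats_boot <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      pick <- sample(ids, replace = TRUE)
      statistic(scores[unlist(split_rows[pick], use.names = FALSE), ,
                       drop = FALSE])
    }, numeric(1))
  })
  qs <- quantile(stats_boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE)
  structure(
    list(estimate = est, ci_low = qs[1], ci_high = qs[2], level = level,
         n_reps = n_reps, seed = seed, resampling_unit = "SUBJECT"),
    class = "bootstrap_result"
  )
}

#' Formatted summary tables for a result bundle
#'
#' @param bundle a [run_analysis()] result.
#' @return (invisibly) a list of tibbles: `item_means`, `subject_means`,
#'   `models`, `exclusion_summary`. Also prints a compact report.
#' @export
report_tables <- function(bundle) {
  stopifnot(inherits(bundle, "result_bundle"))
  tbl <- bundle$score_table
  models <- dplyr::bind_rows(
    dplyr::mutate(model_table(bundle$lmm), model = "score_lmm", .before = 1),
    dplyr::mutate(model_table(bundle$glmm_phase), model = "glmm_phase",
                  .before = 1),
    dplyr::mutate(model_table(bundle$glmm_age), model = "glmm_phase_age",
                  .before = 1)
  )
  excl <- bundle$subject_filter$audit
  cat("== Pair-based difference scores ==\n")
  cat(sprintf("items: grand mean %.3f (%d/%d positive); subjects: grand mean %.3f (%d/%d positive)\n",
              bundle$score_table$grand_item_mean,
              sum(tbl$item_means$mean_score > 0), nrow(tbl$item_means),
              bundle$score_table$grand_subject_mean,
              sum(tbl$subject_means$mean_score > 0),
              nrow(tbl$subject_means)))
  print(bundle$bootstrap$grand_item_mean)
  print(bundle$tests$item_wilcoxon)
  print(bundle$tests$item_sign)
  cat("== Score LMM ==\n")
  print(bundle$lmm)
  cat("== Phase mixed logit ==\n")
  print(bundle$glmm_phase)
  cat(sprintf("phase+age vs phase: chi2(%d) = %.2f, P = %.3g\n",
              bundle$glmm_comparison$df, bundle$glmm_comparison$chisq,
              bundle$glmm_comparison$p_value))
  cat(sprintf("== Exclusions: %d/%d trials excluded; %d/%d subjects retained ==\n",
              bundle$run_info$n_trials_excluded, bundle$run_info$n_trials_in,
              bundle$run_info$n_subjects_retained,
              bundle$run_info$n_subjects_in))
  invisible(list(
    item_means = tbl$item_means,
    subject_means = tbl$subject_means,
    models = models,
    exclusion_summary = excl
  ))
}

#' Write a result bundle to disk
#'
#' Emits the exclusion audit, score tables, model tables, timecourse CSV
#' and figure, and a run manifest recording seeds and versions — every
#' number regenerable from config + inputs alone.
#'
#' @param bundle a [run_analysis()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_exclusion_audit(bundle$exclusions, bundle$subject_filter, dir)
  write_score_table(bundle$score_table, dir)
  tables <- report_tables(bundle)
  readr::write_csv(tables$models, file.path(dir, "model_tables.csv"))
  readr::write_csv(bundle$timecourse, file.path(dir, "timecourse.csv"))
  fig <- plot_timecourse(bundle$timecourse)
  ggplot2::ggsave(file.path(dir, "timecourse.png"), fig, width = 7,
                  height = 4, dpi = 150)
  info <- bundle$run_info
  writeLines(
    c(sprintf("experiment: %s", bundle$config$experiment),
      sprintf("seed: %d", info$seed),
      sprintf("bootstrap_reps: %d", bundle$config$boot_reps),
      sprintf("subjects: %d in, %d retained", info$n_subjects_in,
              info$n_subjects_retained),
      sprintf("trials: %d in, %d excluded", info$n_trials_in,
              info$n_trials_excluded),
      sprintf("gazelex_version: %s", info$package_version),
      sprintf("timestamp_utc: %s", info$timestamp)),
    file.path(dir, "run_manifest.txt")
  )
  invisible(dir)
}
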