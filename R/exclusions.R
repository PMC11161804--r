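#' Trial-level exclusion rules
#'
#' A trial is excluded when any of four criteria holds, and all that apply
#' are recorded (criteria frequently co-occur):
#'
#' * `NO_PRENAMING_LOOK` — the infant never looked to either display during
#'   the pre-naming period `[0, 367)`;
#' * `CRYING` — coders flagged the infant as actively crying;
#' * `MIN_LOOKING` — looking to the two displays during the analysis window
#'   totals strictly less than one third of it (3133/3 ms);
#' * `ADULT_ERROR` — caregiver or experimenter error flagged on the trial.
#'
#' @param spec one-row trial manifest.
#' @param trial the corresponding `aligned_trial`.
#' @return one-row tibble: `trial_id`, `excluded`, `reasons`
#'   (semicolon-joined, empty when retained), plus one logical column per
#'   criterion.
#' @export
classify_trial <- function(spec, trial) {
  pre <- summarize_window(trial, window_prenaming())
  ana <- summarize_window(trial, window_analysis())
  no_pre <- (pre$target_ms + pre$distractor_ms) == 0
  min_look <- (ana$target_ms + ana$distractor_ms) < min_looking_threshold_ms()
  reasons <- c(
    NO_PRENAMING_LOOK = no_pre,
    CRYING = isTRUE(spec$crying_flag),
    MIN_LOOKING = min_look,
    ADULT_ERROR = isTRUE(spec$error_flag)
  )
  tibble::tibble(
    trial_id = spec$trial_id,
    excluded = any(reasons),
    reasons = paste(names(reasons)[reasons], collapse = ";"),
    no_prenaming_look = unname(reasons["NO_PRENAMING_LOOK"]),
    crying = unname(reasons["CRYING"]),
    min_looking = unname(reasons["MIN_LOOKING"]),
    adult_error = unname(reasons["ADULT_ERROR"])
  )
}

#' Classify every trial in a study
#'
#' Vectorised application of [classify_trial()] across a study.
#'
#' @param study a `gaze_study`.
#' @return tibble with one [classify_trial()] row per trial, plus
#'   `subject_id` and `experiment`.
#' @export
classify_study <- function(study) {
  pre <- window_summaries_fast(study, window_prenaming())
  ana <- window_summaries_fast(study, window_analysis())
  no_pre <- (pre$target_ms + pre$distractor_ms) == 0
  min_look <- (ana$target_ms + ana$distractor_ms) < min_looking_threshold_ms()
  crying <- as.logical(study$trials$crying_flag)
  adult <- as.logical(study$trials$error_flag)
  reason_mat <- cbind(NO_PRENAMING_LOOK = no_pre, CRYING = crying,
                      MIN_LOOKING = min_look, ADULT_ERROR = adult)
  reasons <- apply(reason_mat, 1, function(r) {
    paste(colnames(reason_mat)[r], collapse = ";")
  })
  tibble::tibble(
    trial_id = study$trials$trial_id,
    excluded = rowSums(reason_mat) > 0,
    reasons = reasons,
    no_prenaming_look = no_pre,
    crying = crying,
    min_looking = min_look,
    adult_error = adult,
    subject_id = study$trials$subject_id,
    experiment = study$trials$experiment
  )
}

#' Subject-level filtering and exclusion audit
#'
#' A subject is retained when they contribute usable (non-excluded) data on
#' at least half of the experiment's designed test trials (32 for `NOUNS`,
#' 8 for `HONORIFICS`) — the denominator is the designed count, not the
#' number of attended trials.
#'
#' @param study a `gaze_study`.
#' @param exclusions output of [classify_study()].
#' @return list with `retained` / `excluded` subject id vectors and `audit`,
#'   a per-subject tibble of usable counts and per-reason tallies.
#' @export
filter_subjects <- function(study, exclusions) {
  audit <- dplyr::summarise(
    dplyr::group_by(exclusions, .data$subject_id, .data$experiment),
    n_trials = dplyr::n(),
    usable_trial_count = sum(!.data$excluded),
    n_excluded = sum(.data$excluded),
    n_no_prenaming_look = sum(.data$no_prenaming_look),
    n_crying = sum(.data$crying),
    n_min_looking = sum(.data$min_looking),
    n_adult_error = sum(.data$adult_error),
    .groups = "drop"
  )
  audit$designed_trials <- vapply(audit$experiment, designed_trial_count,
                                  integer(1))
  audit$retained <- audit$usable_trial_count >= audit$designed_trials / 2
  list(
    retained = audit$subject_id[audit$retained],
    excluded = audit$subject_id[!audit$retained],
    audit = audit
  )
}

#' Write the exclusion audit trail
#'
#' Two CSVs: a per-trial table (`subject_id`, `trial_id`, `excluded`,
#' semicolon-joined `reasons`, the subject's `usable_trial_count`) and the
#' per-subject audit.
#'
#' @param exclusions [classify_study()] output.
#' @param filter [filter_subjects()] output.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_exclusion_audit <- function(exclusions, filter, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  per_trial <- dplyr::left_join(
    dplyr::select(exclusions, "subject_id", "trial_id", "excluded", "reasons"),
    dplyr::select(filter$audit, "subject_id", "usable_trial_count"),
    by = "subject_id"
  )
  readr::write_csv(per_trial, file.path(dir, "exclusions_trial.csv"))
  readr::write_csv(filter$audit, file.path(dir, "exclusions_subject.csv"))
  invisible(dir)
}
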