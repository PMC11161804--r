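#' Proportion of looking directed to the target
#'
#' The denominator is looking to *either* image only; `AWAY` time is
#' excluded. This is the convention that makes the pair-based difference
#' score exactly symmetric in which image of the pair is designated.
#'
#' @param summary one-row [summarize_window()] result (or anything with
#'   `target_ms` and `distractor_ms`).
#' @return proportion in `[0, 1]`.
#' @export
target_proportion <- function(summary) {
  denom <- summary$target_ms + summary$distractor_ms
  if (any(denom <= 0)) {
    abort(paste0("undefined target proportion (no looking to either image) ",
                 "for trial(s): ",
                 paste(summary$trial_id[denom <= 0], collapse = ", "),
                 "; such trials should have been excluded upstream"),
          class = "gazelex_proportion_error")
  }
  summary$target_ms / denom
}

#' Baseline-corrected score for one image pair
#'
#' The proportion of looking directed to an image on the trial where that
#' image was the *target*, minus the proportion of looking to the same
#' image on the matched trial where it was the *distractor*. Positive
#' values indicate word-driven looking; any stable visual preference for
#' one image cancels. With the either-image denominator, the score equals
#' `p1 + p2 - 1` where `p1`, `p2` are the two trials' target proportions —
#' identical whichever image of the pair is designated.
#'
#' @param when_target window summary of the trial where the designated
#'   image is the target.
#' @param when_distractor window summary of the matched trial where it is
#'   the distractor.
#' @return score in `[-1, 1]`.
#' @export
image_pair_score <- function(when_target, when_distractor) {
  p_target_trial <- target_proportion(when_target)
  p_other_trial <- target_proportion(when_distractor)
  # looking at the designated image on trial 2 = that trial's distractor
  p_target_trial - (1 - p_other_trial)
}

#' Combine image-pair scores into a word-pair score
#'
#' The word-pair score is the mean over the image-pairs with a defined
#' (complete) score; with none complete it is missing — a value, not an
#' error.
#'
#' @param image_pair_scores numeric vector of per-image-pair scores, `NA`
#'   for image-pairs lacking a usable presentation.
#' @return list: `score` (or `NA`), `n_image_pairs_used`.
#' @export
word_pair_score <- function(image_pair_scores) {
  used <- image_pair_scores[!is.na(image_pair_scores)]
  list(
    score = if (length(used) == 0) NA_real_ else mean(used),
    n_image_pairs_used = length(used)
  )
}

#' Pair-based difference scores for a study
#'
#' For every (subject, word pair): each of the two image pairs contributes
#' a score only when *both* of its presentations survive exclusion; the
#' word-pair score is the mean over the contributing image pairs (1 or 2),
#' and is missing (`NA`) when neither image pair is complete. Missingness
#' is a value, not an error.
#'
#' @param study a `gaze_study`.
#' @param exclusions [classify_study()] output; pass `NULL` to score all
#'   trials.
#' @param window the scoring window (default the analysis window).
#' @param aligned optional pre-computed [align_study()] result.
#' @return tibble: `subject_id`, `word_pair_id`, `score`,
#'   `n_image_pairs_used`, `trial_ids` (semicolon-joined provenance).
#' @export
pair_scores <- function(study, exclusions = NULL, window = window_analysis(),
                        aligned = NULL) {
  summaries <- if (is.null(aligned)) {
    window_summaries_fast(study, window)
  } else {
    summarize_study_window(aligned, window)
  }
  usable <- if (is.null(exclusions)) {
    summaries$trial_id
  } else {
    exclusions$trial_id[!exclusions$excluded]
  }
  trials <- dplyr::select(study$trials, "subject_id", "trial_id",
                          "word_pair_id", "image_pair_index")
  df <- dplyr::left_join(trials, summaries,
                         by = c("subject_id", "trial_id"))
  df$usable <- df$trial_id %in% usable

  cell_score <- function(d) {
    # d: the two presentations of one image pair for one subject
    if (nrow(d) != 2 || !all(d$usable)) {
      return(tibble::tibble(score = NA_real_, trial_ids = NA_character_))
    }
    p <- target_proportion(d)
    tibble::tibble(score = p[1] + p[2] - 1,
                   trial_ids = paste(d$trial_id, collapse = ";"))
  }
  by_image_pair <- dplyr::reframe(
    dplyr::group_by(df, .data$subject_id, .data$word_pair_id,
                    .data$image_pair_index),
    cell_score(dplyr::pick(dplyr::everything()))
  )
  dplyr::summarise(
    dplyr::group_by(by_image_pair, .data$subject_id, .data$word_pair_id),
    n_image_pairs_used = sum(!is.na(.data$score)),
    trial_ids = paste(stats::na.omit(.data$trial_ids), collapse = ";"),
    score = if (all(is.na(.data$score))) NA_real_ else
      mean(.data$score, na.rm = TRUE),
    .groups = "drop"
  )
}

#' Aggregate pair scores to item and subject means
#'
#' Item means average the defined scores for a word pair over subjects;
#' subject means average a subject's defined word-pair scores over items.
#' Grand means are unweighted means of those marginals.
#'
#' @param scores [pair_scores()] output.
#' @return list of class `score_table`: `scores` (defined rows only),
#'   `item_means`, `subject_means`, `grand_item_mean`, `grand_subject_mean`.
#' @export
aggregate_scores <- function(scores) {
  defined <- scores[!is.na(scores$score), , drop = FALSE]
  if (nrow(defined) == 0) {
    abort("no defined pair scores to aggregate",
          class = "gazelex_validation_error")
  }
  item_means <- dplyr::summarise(
    dplyr::group_by(defined, .data$word_pair_id),
    mean_score = mean(.data$score), n_subjects = dplyr::n(), .groups = "drop"
  )
  subject_means <- dplyr::summarise(
    dplyr::group_by(defined, .data$subject_id),
    mean_score = mean(.data$score), n_pairs = dplyr::n(), .groups = "drop"
  )
  structure(
    list(
      scores = defined,
      item_means = item_means,
      subject_means = subject_means,
      grand_item_mean = mean(item_means$mean_score),
      grand_subject_mean = mean(subject_means$mean_score)
    ),
    class = "score_table"
  )
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf(
    "<score_table> %d scores | %d items (grand mean %.3f) | %d subjects (grand mean %.3f)\n",
    nrow(x$scores), nrow(x$item_means), x$grand_item_mean,
    nrow(x$subject_means), x$grand_subject_mean
  ))
  invisible(x)
}

#' Write score tables as CSV
#' @param table a `score_table`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_score_table <- function(table, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(table$scores, file.path(dir, "pair_scores.csv"))
  readr::write_csv(table$item_means, file.path(dir, "item_means.csv"))
  readr::write_csv(table$subject_means, file.path(dir, "subject_means.csv"))
  invisible(dir)
}
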