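#' Construct a table of coded looks
#'
#' A look record is one manually coded gaze interval: the infant looked
#' `LEFT`, `RIGHT`, or `AWAY` over the half-open interval
#' `[onset_ms, offset_ms)` on the session clock (milliseconds, clock starts
#' at 0). Gaps between records are permitted and are treated as `AWAY`
#' downstream: manual coders annotate visible fixations only.
#'
#' @param trial_id character vector of trial identifiers.
#' @param direction gaze direction codes; normalised via [normalize_direction()].
#' @param onset_ms,offset_ms non-negative interval bounds in ms (session clock).
#' @return A tibble with columns `trial_id`, `direction`, `onset_ms`,
#'   `offset_ms`, sorted by `(trial_id, onset_ms)`.
#' @examples
#' look_records("t01", "L", 0, 500)
#' @export
look_records <- function(trial_id, direction, onset_ms, offset_ms) {
  looks <- tibble::tibble(
    trial_id = as.character(trial_id),
    direction = normalize_direction(direction),
    onset_ms = as.numeric(onset_ms),
    offset_ms = as.numeric(offset_ms)
  )
  validate_looks(looks)
}

#' Validate look records
#'
#' Enforces the look-record invariants: `offset_ms > onset_ms`, non-negative
#' onsets, and no overlap between records within a trial.
#'
#' @param looks a tibble as produced by [look_records()].
#' @param context optional file/line provenance (integer vector of source line
#'   numbers, parallel to rows) used to make error messages actionable.
#' @return the validated tibble, sorted by `(trial_id, onset_ms)`.
#' @export
validate_looks <- function(looks, context = NULL) {
  required <- c("trial_id", "direction", "onset_ms", "offset_ms")
  missing_cols <- setdiff(required, names(looks))
  if (length(missing_cols) > 0) {
    abort(paste0("look table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "gazelex_format_error")
  }
  line <- if (is.null(context)) seq_len(nrow(looks)) else context

  bad_order <- which(!(looks$offset_ms > looks$onset_ms))
  if (length(bad_order) > 0) {
    abort(paste0("look offset must exceed onset; offending row(s)/line(s): ",
                 paste(line[bad_order], collapse = ", ")),
          class = "gazelex_validation_error")
  }
  bad_neg <- which(looks$onset_ms < 0)
  if (length(bad_neg) > 0) {
    abort(paste0("look onsets must be non-negative; offending row(s)/line(s): ",
                 paste(line[bad_neg], collapse = ", ")),
          class = "gazelex_validation_error")
  }

  ord <- order(looks$trial_id, looks$onset_ms)
  looks <- looks[ord, , drop = FALSE]
  # overlap check within trial (records are now sorted by onset)
  same_trial <- looks$trial_id[-1] == looks$trial_id[-nrow(looks)]
  if (nrow(looks) > 1) {
    overlap <- same_trial & looks$onset_ms[-1] < looks$offset_ms[-nrow(looks)]
    if (any(overlap)) {
      bad <- unique(looks$trial_id[-1][overlap])
      abort(paste0("overlapping looks within trial(s): ",
                   paste(bad, collapse = ", ")),
            class = "gazelex_validation_error")
    }
  }
  tibble::as_tibble(looks)
}

#' Normalise gaze direction codes
#'
#' Maps common annotation spellings (`"L"`, `"left"`, `"R"`, `"A"`, `"."`,
#' `""`) onto the canonical `LEFT` / `RIGHT` / `AWAY` codes.
#'
#' @param x character vector of raw direction codes.
#' @return character vector over `c("LEFT", "RIGHT", "AWAY")`.
#' @export
normalize_direction <- function(x) {
  key <- toupper(trimws(as.character(x)))
  map <- c(
    L = "LEFT", LEFT = "LEFT",
    R = "RIGHT", RIGHT = "RIGHT",
    A = "AWAY", AWAY = "AWAY", OFF = "AWAY", "." = "AWAY"
  )
  key[key == ""] <- "AWAY"
  out <- unname(map[key])
  if (anyNA(out)) {
    bad <- unique(key[is.na(out)])
    abort(paste0("unrecognised gaze direction code(s): ",
                 paste(bad, collapse = ", ")),
          class = "gazelex_format_error")
  }
  out
}

#' Construct a trial manifest
#'
#' One row per trial: the design cell (word pair, image pair, target word and
#' side), the target-word onset on the session clock, and contamination flags
#' (infant crying; caregiver/experimenter error).
#'
#' @param df data frame with columns `trial_id`, `experiment`, `word_pair_id`,
#'   `image_pair_index`, `target_word`, `target_side`, `target_onset_ms`,
#'   `crying_flag`, `error_flag` (and optionally `subject_id`).
#' @param check_design enforce that every `(word_pair_id, image_pair_index)`
#'   cell occurs exactly twice, once per target word (the full counterbalanced
#'   design). Disable for deliberately partial manifests.
#' @return a validated tibble in file order (presentation order).
#' @export
trial_manifest <- function(df, check_design = TRUE) {
  required <- c("trial_id", "experiment", "word_pair_id", "image_pair_index",
                "target_word", "target_side", "target_onset_ms",
                "crying_flag", "error_flag")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("trial manifest is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "gazelex_format_error")
  }
  out <- tibble::as_tibble(df)
  out$trial_id <- as.character(out$trial_id)
  out$experiment <- toupper(as.character(out$experiment))
  if (!all(out$experiment %in% EXPERIMENT_LEVELS)) {
    abort("experiment must be NOUNS or HONORIFICS",
          class = "gazelex_format_error")
  }
  out$target_side <- normalize_direction(out$target_side)
  if (any(out$target_side == "AWAY")) {
    abort("target_side must be LEFT or RIGHT", class = "gazelex_format_error")
  }
  out$image_pair_index <- as.integer(out$image_pair_index)
  if (!all(out$image_pair_index %in% c(1L, 2L))) {
    abort("image_pair_index must be 1 or 2", class = "gazelex_format_error")
  }
  out$target_onset_ms <- as.numeric(out$target_onset_ms)
  out$crying_flag <- as.logical(out$crying_flag)
  out$error_flag <- as.logical(out$error_flag)
  if (anyDuplicated(out$trial_id)) {
    abort("trial_id values must be unique within a manifest",
          class = "gazelex_validation_error")
  }
  if (check_design) {
    check_manifest_design(out)
  }
  out
}

# Each (word_pair, image_pair) cell must appear exactly twice, once with each
# member of the pair as target.
check_manifest_design <- function(specs) {
  key_cols <- c("word_pair_id", "image_pair_index")
  if ("subject_id" %in% names(specs)) key_cols <- c("subject_id", key_cols)
  cells <- dplyr::summarise(
    dplyr::group_by(specs, dplyr::across(dplyr::all_of(key_cols))),
    n = dplyr::n(),
    n_targets = dplyr::n_distinct(.data$target_word),
    .groups = "drop"
  )
  bad <- cells[cells$n != 2L | cells$n_targets != 2L, , drop = FALSE]
  if (nrow(bad) > 0) {
    labs <- paste0(bad$word_pair_id, "/image-pair ", bad$image_pair_index)
    abort(paste0("design error: each (word pair, image pair) must occur ",
                 "exactly twice with distinct targets; offending cell(s): ",
                 paste(unique(labs), collapse = ", ")),
          class = "gazelex_design_error")
  }
  invisible(specs)
}

#' Construct subject metadata
#'
#' @param subject_id character identifiers.
#' @param age_months positive ages in months; values outside the plausible
#'   infant range (3-24 mo) raise a validation warning, not an error.
#' @return tibble with `subject_id`, `age_months`.
#' @export
subject_meta <- function(subject_id, age_months) {
  meta <- tibble::tibble(
    subject_id = as.character(subject_id),
    age_months = as.numeric(age_months)
  )
  if (any(meta$age_months <= 0)) {
    abort("age_months must be positive", class = "gazelex_validation_error")
  }
  out_of_range <- meta$age_months < 3 | meta$age_months > 24
  if (any(out_of_range)) {
    warn(paste0("age_months outside plausible infant range (3-24 mo) for: ",
                paste(meta$subject_id[out_of_range], collapse = ", ")))
  }
  if (anyDuplicated(meta$subject_id)) {
    abort("duplicate subject_id in metadata", class = "gazelex_validation_error")
  }
  meta
}

#' Assemble a single-subject session
#'
#' Binds one subject's metadata, trial manifest and look records into a
#' `gaze_session`, checking cross-references: every look must belong to a
#' manifest trial, and the manifest must describe a single subject. Trials
#' with zero looks are retained — they feed the exclusion logic downstream.
#'
#' @param meta one-row tibble from [subject_meta()].
#' @param specs manifest from [trial_manifest()] for this subject.
#' @param looks look table from [look_records()] / [read_looks()].
#' @param check_design passed to [trial_manifest()] re-validation.
#' @return object of class `gaze_session`: list with `subject`, `trials`,
#'   `looks`.
#' @export
assemble_session <- function(meta, specs, looks, check_design = TRUE) {
  if (nrow(meta) != 1) {
    abort("assemble_session expects metadata for exactly one subject",
          class = "gazelex_validation_error")
  }
  if ("subject_id" %in% names(specs) &&
      length(unique(specs$subject_id)) > 1) {
    abort("manifest mixes trials from more than one subject",
          class = "gazelex_validation_error")
  }
  specs <- trial_manifest(specs, check_design = check_design)
  looks <- validate_looks(looks)
  orphans <- setdiff(unique(looks$trial_id), specs$trial_id)
  if (length(orphans) > 0) {
    abort(paste0("look records reference unknown trial_id(s): ",
                 paste(orphans, collapse = ", ")),
          class = "gazelex_validation_error")
  }
  # flag trials whose coded looks all end before the target word came on
  has_looks <- specs$trial_id %in% looks$trial_id
  if (any(has_looks)) {
    last_off <- tapply(looks$offset_ms, looks$trial_id, max)
    onset <- setNames(specs$target_onset_ms, specs$trial_id)
    late <- names(last_off)[last_off[names(last_off)] <=
                              onset[names(last_off)]]
    if (length(late) > 0) {
      warn(paste0("target onset falls after the last coded look in trial(s): ",
                  paste(late, collapse = ", ")))
    }
  }
  structure(
    list(subject = meta, trials = specs, looks = looks),
    class = "gaze_session"
  )
}

#' Bind sessions into a study
#'
#' A `gaze_study` is the flat, multi-subject view of a set of sessions:
#' three tibbles (`subjects`, `trials`, `looks`) keyed by `subject_id` and
#' `trial_id`. Most pipeline functions take a study.
#'
#' @param sessions list of `gaze_session` objects (unique subjects).
#' @return object of class `gaze_study`.
#' @export
bind_sessions <- function(sessions) {
  stopifnot(all(vapply(sessions, inherits, logical(1), "gaze_session")))
  subjects <- dplyr::bind_rows(lapply(sessions, `[[`, "subject"))
  if (anyDuplicated(subjects$subject_id)) {
    abort("duplicate subjects across sessions", class = "gazelex_validation_error")
  }
  trials <- dplyr::bind_rows(lapply(sessions, function(s) {
    dplyr::mutate(s$trials, subject_id = s$subject$subject_id, .before = 1)
  }))
  looks <- dplyr::bind_rows(lapply(sessions, function(s) {
    dplyr::mutate(s$looks, subject_id = s$subject$subject_id, .before = 1)
  }))
  structure(
    list(subjects = subjects, trials = trials, looks = looks),
    class = "gaze_study"
  )
}

#' @export
print.gaze_session <- function(x, ...) {
  cat(sprintf("<gaze_session> subject %s (%.2f mo): %d trials, %d looks\n",
              x$subject$subject_id, x$subject$age_months,
              nrow(x$trials), nrow(x$looks)))
  invisible(x)
}

#' @export
print.gaze_study <- function(x, ...) {
  cat(sprintf("<gaze_study> %d subjects, %d trials, %d looks (%s)\n",
              nrow(x$subjects), nrow(x$trials), nrow(x$looks),
              paste(unique(x$trials$experiment), collapse = "+")))
  invisible(x)
}

#' Split a study back into sessions
#' @param study a `gaze_study`.
#' @return named list of `gaze_session` objects.
#' @export
study_sessions <- function(study) {
  stopifnot(inherits(study, "gaze_study"))
  ids <- study$subjects$subject_id
  out <- lapply(ids, function(id) {
    assemble_session(
      study$subjects[study$subjects$subject_id == id, , drop = FALSE],
      dplyr::filter(study$trials, .data$subject_id == id),
      dplyr::select(
        dplyr::filter(study$looks, .data$subject_id == id), -"subject_id"
      ),
      check_design = FALSE
    )
  })
  names(out) <- ids
  out
}
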