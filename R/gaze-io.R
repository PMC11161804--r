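#' Annotation dialect registry
#'
#' The pipeline consumes delimited exports of manual gaze coding. The
#' canonical dialect is a UTF-8 comma-separated table with a header row and
#' columns `trial_id, direction, onset_ms, offset_ms`. Coding tools export
#' in many shapes, so additional dialects can be registered: a dialect is a
#' function `path -> data.frame` with those four columns (raw direction codes
#' are fine; they are normalised afterwards).
#'
#' @param name dialect name.
#' @param reader function of `path` returning a data frame with the four
#'   canonical columns.
#' @return `register_look_dialect()` returns the reader invisibly;
#'   `look_dialects()` returns the names of registered dialects.
#' @export
register_look_dialect <- function(name, reader) {
  stopifnot(is.character(name), length(name) == 1, is.function(reader))
  .dialects[[name]] <- reader
  invisible(reader)
}

.dialects <- new.env(parent = emptyenv())

#' @rdname register_look_dialect
#' @export
look_dialects <- function() ls(.dialects)

read_delim_quiet <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "gazelex_format_error")
  }
  out <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    name_repair = "minimal"),
    error = function(e) {
      abort(paste0("could not parse ", path, ": ", conditionMessage(e)),
            class = "gazelex_format_error")
    }
  )
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(paste0("malformed row(s) in ", path, " at line(s): ",
                 paste(unique(probs$row + 1L), collapse = ", ")),
          class = "gazelex_format_error")
  }
  out
}

local({
  .dialects[["canonical"]] <- function(path) read_delim_quiet(path)
})

#' Read coded looks from file
#'
#' @param path delimited text file of look records.
#' @param dialect registered dialect name (default `"canonical"`).
#' @return validated look tibble sorted by `(trial_id, onset_ms)`; see
#'   [look_records()]. A `subject_id` column, if present, is carried through.
#' @export
read_looks <- function(path, dialect = "canonical") {
  if (!dialect %in% look_dialects()) {
    abort(paste0("unknown annotation dialect: ", dialect,
                 " (registered: ", paste(look_dialects(), collapse = ", "), ")"),
          class = "gazelex_format_error")
  }
  raw <- .dialects[[dialect]](path)
  required <- c("trial_id", "direction", "onset_ms", "offset_ms")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "gazelex_format_error")
  }
  raw$direction <- normalize_direction(raw$direction)
  raw$trial_id <- as.character(raw$trial_id)
  raw$onset_ms <- as.numeric(raw$onset_ms)
  raw$offset_ms <- as.numeric(raw$offset_ms)
  raw$.line <- seq_len(nrow(raw)) + 1L  # header is line 1
  if ("subject_id" %in% names(raw)) {
    raw$subject_id <- as.character(raw$subject_id)
    out <- dplyr::bind_rows(lapply(
      split(raw, raw$subject_id),
      function(d) validate_looks(d, context = d$.line)
    ))
    out$.line <- NULL
    tibble::as_tibble(out[order(out$subject_id, out$trial_id, out$onset_ms), ])
  } else {
    out <- validate_looks(raw, context = raw$.line)
    out$.line <- NULL
    out
  }
}

#' Read a trial manifest from file
#'
#' File order is preserved as the presentation order. Design completeness
#' (each image-pair seen twice, once per target) is enforced per subject.
#'
#' @param path CSV with the [trial_manifest()] column contract.
#' @param check_design enforce the counterbalanced-design invariant.
#' @return validated manifest tibble.
#' @export
read_trial_manifest <- function(path, check_design = TRUE) {
  trial_manifest(read_delim_quiet(path), check_design = check_design)
}

#' Read subject metadata from file
#' @param path CSV with columns `subject_id`, `age_months`.
#' @return validated tibble; see [subject_meta()].
#' @export
read_subjects <- function(path) {
  raw <- read_delim_quiet(path)
  missing_cols <- setdiff(c("subject_id", "age_months"), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "gazelex_format_error")
  }
  subject_meta(raw$subject_id, raw$age_months)
}

#' Read a whole study from a directory
#'
#' Expects `subjects.csv`, `manifest.csv` and `looks.csv` in the canonical
#' dialect, with `subject_id` columns linking the three tables (the layout
#' [write_study()] produces).
#'
#' @param dir directory containing the three CSVs.
#' @param check_design enforce the counterbalanced-design invariant.
#' @return a `gaze_study`.
#' @export
read_study <- function(dir, check_design = TRUE) {
  subjects <- read_subjects(file.path(dir, "subjects.csv"))
  trials <- read_trial_manifest(file.path(dir, "manifest.csv"),
                                check_design = check_design)
  looks <- read_looks(file.path(dir, "looks.csv"))
  if (!"subject_id" %in% names(trials) || !"subject_id" %in% names(looks)) {
    abort("study-level manifest and looks files need a subject_id column",
          class = "gazelex_format_error")
  }
  sessions <- lapply(subjects$subject_id, function(id) {
    assemble_session(
      subjects[subjects$subject_id == id, , drop = FALSE],
      dplyr::filter(trials, .data$subject_id == id),
      dplyr::select(dplyr::filter(looks, .data$subject_id == id),
                    -"subject_id"),
      check_design = check_design
    )
  })
  bind_sessions(sessions)
}

#' Write a study to a directory
#'
#' Canonical CSV writers for the three study tables; the output round-trips
#' through [read_study()] field-for-field.
#'
#' @param study a `gaze_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "gaze_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(study$subjects, file.path(dir, "subjects.csv"))
  readr::write_csv(study$trials, file.path(dir, "manifest.csv"))
  readr::write_csv(study$looks, file.path(dir, "looks.csv"))
  invisible(dir)
}
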