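#' Analysis windows
#'
#' Windows are half-open intervals `[start_ms, end_ms)` on the
#' onset-aligned clock (0 = target-word onset). The two standard windows
#' are the pre-naming period `[0, 367)` — 367 ms allows for infant
#' saccade-programming latency, so looks launched before that cannot yet
#' reflect the word — and the analysis window `[367, 3500)`.
#'
#' @param name window label.
#' @param start_ms,end_ms bounds in ms, `end_ms > start_ms`.
#' @return a `gaze_window` (named list with `name`, `start_ms`, `end_ms`).
#' @export
gaze_window <- function(name, start_ms, end_ms) {
  stopifnot(is.numeric(start_ms), is.numeric(end_ms))
  if (!(end_ms > start_ms)) {
    abort("window end must exceed start", class = "gazelex_validation_error")
  }
  structure(list(name = name, start_ms = start_ms, end_ms = end_ms),
            class = "gaze_window")
}

#' @rdname gaze_window
#' @export
window_prenaming <- function() gaze_window("PRENAMING", 0, 367)

#' @rdname gaze_window
#' @export
window_analysis <- function() gaze_window("ANALYSIS", 367, 3500)

#' @rdname gaze_window
#' @param range_ms plot range for the timecourse window.
#' @export
window_plot <- function(range_ms = c(-1000, 3500)) {
  gaze_window("PLOT", range_ms[1], range_ms[2])
}

window_duration <- function(window) window$end_ms - window$start_ms

# Looking below one third of the analysis window excludes a trial. Kept as
# the exact rational 3133/3, never pre-rounded.
min_looking_threshold_ms <- function() 3133 / 3

#' Align a trial's looks to target-word onset
#'
#' Shifts all look times by `-target_onset_ms` and relabels directions as
#' gaze roles: the side named by `target_side` becomes `TARGET`, the other
#' side `DISTRACTOR`, `AWAY` stays `AWAY`. Looks spanning the onset are not
#' split; pre-onset times are simply negative.
#'
#' @param spec one-row trial manifest (a [trial_manifest()] row).
#' @param looks look records for that trial (possibly empty).
#' @return an `aligned_trial`: list with `spec` and `looks` (tibble with
#'   `role`, `onset_ms`, `offset_ms` relative to onset).
#' @export
align_trial <- function(spec, looks) {
  stopifnot(nrow(spec) == 1)
  if (nrow(looks) > 0 && !all(looks$trial_id == spec$trial_id)) {
    abort("looks do not belong to the trial being aligned",
          class = "gazelex_validation_error")
  }
  role <- look_role(looks$direction, spec$target_side)
  aligned <- tibble::tibble(
    role = role,
    onset_ms = looks$onset_ms - spec$target_onset_ms,
    offset_ms = looks$offset_ms - spec$target_onset_ms
  )
  structure(list(spec = spec, looks = aligned), class = "aligned_trial")
}

# Pure role map: direction x target side -> TARGET/DISTRACTOR/AWAY.
look_role <- function(direction, target_side) {
  ifelse(direction == "AWAY", "AWAY",
         ifelse(direction == target_side, "TARGET", "DISTRACTOR"))
}

#' Align every trial in a study
#'
#' @param study a `gaze_study`.
#' @return named list of `aligned_trial` objects, one per trial, in manifest
#'   order.
#' @export
align_study <- function(study) {
  stopifnot(inherits(study, "gaze_study"))
  looks_by_trial <- split(study$looks, study$looks$trial_id)
  empty <- study$looks[0, , drop = FALSE]
  out <- lapply(seq_len(nrow(study$trials)), function(i) {
    spec <- study$trials[i, , drop = FALSE]
    lk <- looks_by_trial[[spec$trial_id]]
    if (is.null(lk)) lk <- empty
    align_trial(spec, lk)
  })
  names(out) <- study$trials$trial_id
  out
}

#' Summarise looking within a window
#'
#' Clips each aligned look to the window and sums durations by role.
#' Uncoded time is absorbed into `away_ms`, so the three roles always sum
#' exactly to the window duration.
#'
#' @param trial an `aligned_trial`.
#' @param window a `gaze_window`.
#' @return one-row tibble: `trial_id`, `window`, `target_ms`,
#'   `distractor_ms`, `away_ms`.
#' @export
summarize_window <- function(trial, window) {
  looks <- trial$looks
  dur <- window_duration(window)
  clipped <- pmax(
    0,
    pmin(looks$offset_ms, window$end_ms) - pmax(looks$onset_ms, window$start_ms)
  )
  target_ms <- sum(clipped[looks$role == "TARGET"])
  distractor_ms <- sum(clipped[looks$role == "DISTRACTOR"])
  coded_away <- sum(clipped[looks$role == "AWAY"])
  if (target_ms + distractor_ms + coded_away > dur + 1e-9) {
    abort("looks overlap within the window; validate looks first",
          class = "gazelex_validation_error")
  }
  tibble::tibble(
    trial_id = trial$spec$trial_id,
    window = window$name,
    target_ms = target_ms,
    distractor_ms = distractor_ms,
    away_ms = dur - target_ms - distractor_ms
  )
}

#' Summarise a window for every trial in a study
#'
#' @param aligned list of `aligned_trial` from [align_study()].
#' @param window a `gaze_window`.
#' @return tibble with one row per trial (plus `subject_id` when present in
#'   the manifest).
#' @export
summarize_study_window <- function(aligned, window) {
  out <- dplyr::bind_rows(lapply(aligned, summarize_window, window = window))
  subj <- vapply(aligned, function(a) {
    if ("subject_id" %in% names(a$spec)) a$spec$subject_id else NA_character_
  }, character(1))
  dplyr::mutate(out, subject_id = unname(subj), .before = 1)
}

#' Reduce a window to a sequence of gaze-state bins
#'
#' Tiles the window with consecutive `bin_ms` bins (trailing partial bin
#' dropped) and labels each bin with the role occupying the majority of it.
#' Ties are broken toward the role active at the instant the bin starts;
#' uncoded time counts as `AWAY`.
#'
#' @param trial an `aligned_trial`.
#' @param window a `gaze_window`.
#' @param bin_ms bin width in ms (default 20, the conventional bin for this
#'   paradigm at 60 FPS coding).
#' @return character vector of states over
#'   `c("TARGET", "DISTRACTOR", "AWAY")`, of length
#'   `floor(window_duration / bin_ms)`.
#' @export
bin_window <- function(trial, window, bin_ms = 20) {
  dur <- window_duration(window)
  if (bin_ms >= dur) {
    abort("bin_ms must be smaller than the window duration",
          class = "gazelex_validation_error")
  }
  n_bins <- floor(dur / bin_ms)
  occupancy <- bin_occupancy(trial$looks, window$start_ms, bin_ms, n_bins)
  label_bins(occupancy, trial$looks, window$start_ms, bin_ms, n_bins)
}

# Per-bin coded occupancy (ms) of TARGET and DISTRACTOR; AWAY is the
# remainder (coded AWAY looks and uncoded gaps are equivalent downstream).
bin_occupancy <- function(looks, start_ms, bin_ms, n_bins) {
  tgt <- numeric(n_bins)
  dst <- numeric(n_bins)
  end_ms <- start_ms + n_bins * bin_ms
  keep <- looks$role != "AWAY" & looks$offset_ms > start_ms &
    looks$onset_ms < end_ms
  lk <- looks[keep, , drop = FALSE]
  for (i in seq_len(nrow(lk))) {
    a <- max(lk$onset_ms[i], start_ms)
    b <- min(lk$offset_ms[i], end_ms)
    first <- floor((a - start_ms) / bin_ms)
    last <- ceiling((b - start_ms) / bin_ms) - 1
    idx <- first:last
    lo <- start_ms + idx * bin_ms
    ov <- pmin(b, lo + bin_ms) - pmax(a, lo)
    if (lk$role[i] == "TARGET") {
      tgt[idx + 1] <- tgt[idx + 1] + ov
    } else {
      dst[idx + 1] <- dst[idx + 1] + ov
    }
  }
  list(target = tgt, distractor = dst, away = bin_ms - tgt - dst)
}

label_bins <- function(occupancy, looks, start_ms, bin_ms, n_bins) {
  m <- cbind(TARGET = occupancy$target, DISTRACTOR = occupancy$distractor,
             AWAY = occupancy$away)
  best <- m >= apply(m, 1, max) - 1e-9
  n_best <- rowSums(best)
  states <- ROLE_LEVELS[max.col(m, ties.method = "first")]
  ties <- which(n_best > 1)
  if (length(ties) > 0) {
    starts <- start_ms + (ties - 1) * bin_ms
    at_start <- role_at(looks, starts)
    for (j in seq_along(ties)) {
      k <- ties[j]
      cand <- ROLE_LEVELS[best[k, ]]
      if (at_start[j] %in% cand) {
        states[k] <- at_start[j]
      } else {
        # no maximal role active at bin start: take the maximal role that
        # becomes active first within the bin (AWAY last in role order)
        states[k] <- cand[which.max(m[k, cand])]
        first_on <- vapply(cand, function(r) {
          on <- looks$onset_ms[looks$role == r &
                                 looks$offset_ms > starts[j] &
                                 looks$onset_ms < starts[j] + bin_ms]
          if (length(on) == 0) Inf else min(on)
        }, numeric(1))
        if (any(is.finite(first_on))) states[k] <- cand[which.min(first_on)]
      }
    }
  }
  states
}

# Role active at each queried instant (AWAY when uncoded).
role_at <- function(looks, t) {
  vapply(t, function(x) {
    hit <- looks$role[looks$onset_ms <= x & looks$offset_ms > x]
    if (length(hit) == 0) "AWAY" else hit[1]
  }, character(1))
}

# Flat onset-aligned look table: one row per look with its gaze role and
# times relative to target-word onset. Vectorised equivalent of
# align_study(); the per-trial functions remain the reference
# implementation.
flat_aligned_looks <- function(study) {
  lk <- dplyr::inner_join(
    study$looks,
    dplyr::select(study$trials, "trial_id", "target_onset_ms", "target_side"),
    by = "trial_id"
  )
  tibble::tibble(
    subject_id = lk$subject_id,
    trial_id = lk$trial_id,
    role = look_role(lk$direction, lk$target_side),
    onset_ms = lk$onset_ms - lk$target_onset_ms,
    offset_ms = lk$offset_ms - lk$target_onset_ms
  )
}

# Vectorised window summaries for every trial of a study (including
# zero-look trials). Same contract as summarize_window() row-by-row.
window_summaries_fast <- function(study, window, flat = NULL) {
  if (is.null(flat)) flat <- flat_aligned_looks(study)
  dur <- window_duration(window)
  clip <- pmax(0, pmin(flat$offset_ms, window$end_ms) -
                 pmax(flat$onset_ms, window$start_ms))
  ids <- study$trials$trial_id
  tgt <- dst <- setNames(numeric(length(ids)), ids)
  t_sum <- rowsum(clip[flat$role == "TARGET"],
                  flat$trial_id[flat$role == "TARGET"])
  d_sum <- rowsum(clip[flat$role == "DISTRACTOR"],
                  flat$trial_id[flat$role == "DISTRACTOR"])
  tgt[rownames(t_sum)] <- t_sum[, 1]
  dst[rownames(d_sum)] <- d_sum[, 1]
  tibble::tibble(
    subject_id = study$trials$subject_id,
    trial_id = ids,
    window = window$name,
    target_ms = unname(tgt),
    distractor_ms = unname(dst),
    away_ms = dur - unname(tgt) - unname(dst)
  )
}

# Vectorised majority-rule bin counts per trial for one window. Ties are
# rare (they need exactly equal occupancies); tied trials are recomputed
# through the reference bin_window() path.
bin_counts_fast <- function(study, window, bin_ms, flat = NULL) {
  if (is.null(flat)) flat <- flat_aligned_looks(study)
  n_bins <- floor(window_duration(window) / bin_ms)
  start <- window$start_ms
  end <- start + n_bins * bin_ms
  ids <- study$trials$trial_id
  n_trials <- length(ids)

  lk <- flat[flat$role != "AWAY" & flat$offset_ms > start &
               flat$onset_ms < end, , drop = FALSE]
  a <- pmax(lk$onset_ms, start)
  b <- pmin(lk$offset_ms, end)
  first <- floor((a - start) / bin_ms)
  last <- ceiling((b - start) / bin_ms) - 1
  nb <- last - first + 1L
  row_rep <- rep.int(seq_len(nrow(lk)), nb)
  bin_idx <- sequence(nb) - 1L + rep.int(first, nb)
  lo <- start + bin_idx * bin_ms
  ov <- pmin(b[row_rep], lo + bin_ms) - pmax(a[row_rep], lo)
  cell <- (match(lk$trial_id, ids)[row_rep] - 1L) * n_bins + bin_idx + 1L

  occ_t <- numeric(n_trials * n_bins)
  occ_d <- numeric(n_trials * n_bins)
  is_t <- lk$role[row_rep] == "TARGET"
  if (any(is_t)) {
    s <- rowsum(ov[is_t], cell[is_t])
    occ_t[as.integer(rownames(s))] <- s[, 1]
  }
  if (any(!is_t)) {
    s <- rowsum(ov[!is_t], cell[!is_t])
    occ_d[as.integer(rownames(s))] <- s[, 1]
  }
  occ_a <- bin_ms - occ_t - occ_d
  top <- pmax(occ_t, occ_d, occ_a)
  eps <- 1e-9
  tied <- (occ_t >= top - eps) + (occ_d >= top - eps) +
    (occ_a >= top - eps) > 1
  state_t <- occ_t >= top - eps & !tied
  state_d <- occ_d >= top - eps & !tied

  trial_of_cell <- rep(seq_len(n_trials), each = n_bins)
  counts <- tibble::tibble(
    subject_id = study$trials$subject_id,
    trial_id = ids,
    target_bins = as.integer(rowsum(as.numeric(state_t), trial_of_cell)[, 1]),
    distractor_bins =
      as.integer(rowsum(as.numeric(state_d), trial_of_cell)[, 1])
  )
  tied_trials <- unique(trial_of_cell[tied])
  if (length(tied_trials) > 0) {
    aligned <- align_study(study)
    for (ti in tied_trials) {
      states <- bin_window(aligned[[ids[ti]]], window, bin_ms)
      counts$target_bins[ti] <- sum(states == "TARGET")
      counts$distractor_bins[ti] <- sum(states == "DISTRACTOR")
    }
  }
  counts
}

#' Per-trial bin counts for the pre/post-naming contrast
#'
#' Builds the binomial observations for the phase logit model: for every
#' non-excluded trial and each phase (`PRE` = pre-naming window, `POST` =
#' analysis window), the number of 20 ms bins on the target vs. on the
#' distractor. `AWAY` bins are dropped (they are neither success nor
#' failure).
#'
#' @param study a `gaze_study`.
#' @param exclusions classification from [classify_study()]; excluded trials
#'   are dropped.
#' @param bin_ms bin width in ms.
#' @param prenaming,analysis the two phase windows.
#' @return tibble: `subject_id`, `trial_id`, `word_pair_id`, `phase`,
#'   `target_bins`, `distractor_bins`, `age_months`.
#' @export
phase_bin_counts <- function(study, exclusions = NULL, bin_ms = 20,
                             prenaming = window_prenaming(),
                             analysis = window_analysis()) {
  flat <- flat_aligned_looks(study)
  pre <- bin_counts_fast(study, prenaming, bin_ms, flat)
  post <- bin_counts_fast(study, analysis, bin_ms, flat)
  pre$phase <- "PRE"
  post$phase <- "POST"
  out <- dplyr::bind_rows(pre, post)
  out <- dplyr::left_join(
    out,
    dplyr::select(study$trials, "trial_id", "word_pair_id"),
    by = "trial_id"
  )
  if (!is.null(exclusions)) {
    keep <- exclusions$trial_id[!exclusions$excluded]
    out <- out[out$trial_id %in% keep, , drop = FALSE]
  }
  out$phase <- factor(out$phase, levels = c("PRE", "POST"))
  out <- out[order(match(out$trial_id, study$trials$trial_id), out$phase), ]
  dplyr::left_join(
    out[, c("subject_id", "trial_id", "word_pair_id", "phase",
            "target_bins", "distractor_bins")],
    study$subjects, by = "subject_id"
  )
}
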