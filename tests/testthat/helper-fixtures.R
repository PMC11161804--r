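# Fixtures are built in code. A "manual" study gives full control over
# every look for exclusion / scoring arithmetic; simulated studies come
# from sim_config()/simulate_study().

# Minimal counterbalanced manifest for one subject, written independently
# of the package's own design generator.
manual_manifest <- function(subject_id, experiment = "NOUNS",
                            n_pairs = if (experiment == "NOUNS") 8 else 2,
                            onset_ms = 1000) {
  rows <- list()
  k <- 0
  for (p in seq_len(n_pairs)) {
    for (ip in 1:2) {
      for (m in c("a", "b")) {
        k <- k + 1
        rows[[k]] <- data.frame(
          subject_id = subject_id,
          trial_id = sprintf("%s_t%02d", subject_id, k),
          experiment = experiment,
          word_pair_id = paste0("wp", p),
          image_pair_index = ip,
          target_word = paste0("wp", p, "_", m),
          target_side = if (m == "a") "LEFT" else "RIGHT",
          target_onset_ms = onset_ms,
          crying_flag = FALSE,
          error_flag = FALSE,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

# A look that keeps a trial comfortably clear of every exclusion rule:
# one long target-side look covering pre-naming and most of the analysis
# window (session clock; onset at 1000 ms).
clean_look <- function(trial_id, side = "LEFT", onset = 900, offset = 4400) {
  data.frame(trial_id = trial_id, direction = side,
             onset_ms = onset, offset_ms = offset,
             stringsAsFactors = FALSE)
}

# Single-subject study where every trial is usable; target proportions can
# then be manipulated per trial by replacing looks.
manual_study <- function(subject_id = "sA", experiment = "NOUNS",
                         age = 10, onset_ms = 1000) {
  specs <- manual_manifest(subject_id, experiment, onset_ms = onset_ms)
  looks <- do.call(rbind, lapply(seq_len(nrow(specs)), function(i) {
    lk <- clean_look(specs$trial_id[i], side = specs$target_side[i])
    lk$subject_id <- subject_id
    lk
  }))
  meta <- subject_meta(subject_id, age)
  bind_sessions(list(assemble_session(meta, specs, looks[names(looks) != "subject_id"])))
}

# Study with per-trial target/distractor looking durations (ms within the
# analysis window, both looks placed inside [367, 3500) relative to a
# 1000 ms onset) plus a short pre-naming look so only the intended rules
# fire.
timed_study <- function(durations, subject_id = "sA",
                        experiment = "NOUNS", age = 10) {
  specs <- manual_manifest(subject_id, experiment)
  stopifnot(nrow(durations) == nrow(specs))
  looks <- list()
  for (i in seq_len(nrow(specs))) {
    side <- specs$target_side[i]
    other <- if (side == "LEFT") "RIGHT" else "LEFT"
    tid <- specs$trial_id[i]
    lk <- data.frame(trial_id = character(0), direction = character(0),
                     onset_ms = numeric(0), offset_ms = numeric(0))
    if (!isTRUE(durations$skip_prenaming[i])) {
      lk <- rbind(lk, data.frame(trial_id = tid, direction = side,
                                 onset_ms = 1050, offset_ms = 1150))
    }
    t_ms <- durations$target_ms[i]
    d_ms <- durations$distractor_ms[i]
    if (t_ms > 0) {
      lk <- rbind(lk, data.frame(trial_id = tid, direction = side,
                                 onset_ms = 1400, offset_ms = 1400 + t_ms))
    }
    if (d_ms > 0) {
      lk <- rbind(lk, data.frame(trial_id = tid, direction = other,
                                 onset_ms = 1400 + t_ms,
                                 offset_ms = 1400 + t_ms + d_ms))
    }
    looks[[i]] <- lk
  }
  looks <- do.call(rbind, looks)
  specs$crying_flag <- durations$crying %||% specs$crying_flag
  specs$error_flag <- durations$error %||% specs$error_flag
  meta <- subject_meta(subject_id, age)
  bind_sessions(list(assemble_session(meta, specs, looks)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random look fixture for property tests: non-overlapping looks over a
# session-clock span with onset at 1000 ms, integer-ms endpoints.
random_looks <- function(trial_id, n_looks = 8, span = c(0, 4500)) {
  cuts <- sort(sample(seq(span[1], span[2]), 2 * n_looks))
  on <- cuts[seq(1, 2 * n_looks, 2)]
  off <- cuts[seq(2, 2 * n_looks, 2)]
  keep <- off > on
  data.frame(
    trial_id = trial_id,
    direction = sample(c("LEFT", "RIGHT", "AWAY"), sum(keep), replace = TRUE),
    onset_ms = on[keep], offset_ms = off[keep],
    stringsAsFactors = FALSE
  )
}
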