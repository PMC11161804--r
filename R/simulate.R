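#' Simulation configuration
#'
#' Defines the data-generating gaze process used throughout the package's
#' validation: a first-order Markov chain over per-bin gaze states
#' (`TARGET` / `DISTRACTOR` / `AWAY`). At each bin the infant stays in the
#' current state with probability `stay_prob` (gaze persistence; the
#' geometric run length is `bin_ms / (1 - stay_prob)` ms); otherwise a
#' fresh state is drawn — `AWAY` with probability `away_prob`, else
#' `TARGET` with probability `plogis(eta)`. Before the effective naming
#' point (367 ms, the analysis-window boundary), `eta` is the baseline
#' image-preference contrast; from 367 ms on it additionally includes the
#' knowledge effect, subject and item random effects, and the age term:
#' `eta = pref + beta + u_subject + u_item + age_slope * age_z`.
#'
#' Defaults mirror the field design this package analyses: 21 infants aged
#' 5.33-15.43 months; the nouns design (8 word-pairs x 2 image-pairs x 2
#' targets = 32 trials) or the honorifics design (2 pairs, 8 trials); a
#' post-naming logit shift of 0.25 (odds ratio ~1.28); and occasional
#' crying / experimenter-error contamination.
#'
#' @param n_subjects number of infants.
#' @param age_range_months uniform age range in months.
#' @param design `"NOUNS"` or `"HONORIFICS"`.
#' @param knowledge_effect post-naming logit shift toward the target
#'   (population mean).
#' @param subject_effect_sd,item_effect_sd SDs of the subject / word-pair
#'   random shifts (logit scale).
#' @param age_slope logit shift per standardised age unit, post-naming.
#' @param baseline_image_pref_sd SD of per-image baseline preference
#'   offsets (logit scale); the preference contrast for a trial is the
#'   target image's offset minus the distractor image's.
#' @param away_prob probability that a redrawn state is `AWAY`.
#' @param stay_prob per-bin probability of remaining in the current state.
#' @param crying_prob,error_prob per-trial contamination probabilities.
#' @param bin_ms simulation bin width in ms.
#' @param trial_span_ms coded span relative to target-word onset.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 21,
                       age_range_months = c(5.33, 15.43),
                       design = c("NOUNS", "HONORIFICS"),
                       knowledge_effect = 0.25,
                       subject_effect_sd = 0.3,
                       item_effect_sd = 0.2,
                       age_slope = 0.077,
                       baseline_image_pref_sd = 0.3,
                       away_prob = 0.15,
                       stay_prob = 0.9,
                       crying_prob = 0.02,
                       error_prob = 0.01,
                       bin_ms = 20,
                       trial_span_ms = c(-1000, 3500),
                       seed = 1L) {
  design <- match.arg(design)
  probs <- c(away_prob = away_prob, stay_prob = stay_prob,
             crying_prob = crying_prob, error_prob = error_prob)
  if (any(probs < 0 | probs > 1)) {
    abort("probabilities must lie in [0, 1]", class = "gazelex_validation_error")
  }
  if (stay_prob >= 1) {
    abort("stay_prob must be < 1", class = "gazelex_validation_error")
  }
  structure(
    list(n_subjects = n_subjects, age_range_months = age_range_months,
         design = design, knowledge_effect = knowledge_effect,
         subject_effect_sd = subject_effect_sd,
         item_effect_sd = item_effect_sd, age_slope = age_slope,
         baseline_image_pref_sd = baseline_image_pref_sd,
         away_prob = away_prob, stay_prob = stay_prob,
         crying_prob = crying_prob, error_prob = error_prob,
         bin_ms = bin_ms, trial_span_ms = trial_span_ms,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Full counterbalanced manifest for one subject (before shuffling):
# every (word pair, image pair) cell twice, once per member word.
design_grid <- function(design) {
  n_pairs <- if (design == "NOUNS") 8L else 2L
  grid <- expand.grid(
    word_pair_id = sprintf("%s%d", if (design == "NOUNS") "np" else "hp",
                           seq_len(n_pairs)),
    image_pair_index = 1:2,
    member = c("a", "b"),
    stringsAsFactors = FALSE
  )
  grid$target_word <- paste0(grid$word_pair_id, "_", grid$member)
  grid$target_image <- paste0(grid$word_pair_id, "_ip", grid$image_pair_index,
                              "_", grid$member)
  grid$distractor_image <- paste0(grid$word_pair_id, "_ip",
                                  grid$image_pair_index, "_",
                                  ifelse(grid$member == "a", "b", "a"))
  grid
}

#' Simulate a complete study
#'
#' Draws ages, subject and item effects and per-image baseline preferences,
#' then simulates every trial's gaze chain and converts state runs to look
#' records (runs of `AWAY` become uncoded gaps). The latent truth is
#' returned alongside the data for recovery scoring.
#'
#' @param config a [sim_config()].
#' @return list with `study` (a `gaze_study`) and `truth` (realised
#'   effects, per-trial latent logits, and the config).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(config) {
  n <- config$n_subjects
  subj_ids <- sprintf("s%02d", seq_len(n))
  ages <- runif(n, config$age_range_months[1], config$age_range_months[2])
  age_z <- as.numeric(scale(ages))
  u_subj <- rnorm(n, 0, config$subject_effect_sd)

  grid <- design_grid(config$design)
  pairs <- unique(grid$word_pair_id)
  u_item <- setNames(rnorm(length(pairs), 0, config$item_effect_sd), pairs)
  images <- unique(c(grid$target_image, grid$distractor_image))
  pref <- setNames(rnorm(length(images), 0, config$baseline_image_pref_sd),
                   images)

  onset_ms <- -config$trial_span_ms[1]
  trials <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    g <- grid[sample.int(nrow(grid)), , drop = FALSE]  # presentation order
    tibble::tibble(
      subject_id = subj_ids[i],
      trial_id = sprintf("%s_t%02d", subj_ids[i], seq_len(nrow(g))),
      experiment = config$design,
      word_pair_id = g$word_pair_id,
      image_pair_index = g$image_pair_index,
      target_word = g$target_word,
      target_image = g$target_image,
      distractor_image = g$distractor_image,
      target_side = sample(c("LEFT", "RIGHT"), nrow(g), replace = TRUE),
      target_onset_ms = onset_ms,
      crying_flag = runif(nrow(g)) < config$crying_prob,
      error_flag = runif(nrow(g)) < config$error_prob
    )
  }))
  subj_idx <- match(trials$subject_id, subj_ids)
  eta_pre <- unname(pref[trials$target_image] -
                      pref[trials$distractor_image])
  eta_post <- eta_pre + config$knowledge_effect +
    u_subj[subj_idx] + unname(u_item[trials$word_pair_id]) +
    config$age_slope * age_z[subj_idx]

  states <- simulate_gaze_chains(config, eta_pre, eta_post)
  looks <- states_to_looks(states, trials, config)

  study <- structure(
    list(
      subjects = tibble::tibble(subject_id = subj_ids, age_months = ages),
      trials = trials,
      looks = looks
    ),
    class = "gaze_study"
  )
  truth <- list(
    config = config,
    subjects = tibble::tibble(subject_id = subj_ids, age_months = ages,
                              age_z = age_z, u_subject = u_subj),
    items = tibble::tibble(word_pair_id = pairs, u_item = unname(u_item)),
    image_prefs = tibble::tibble(image = images, pref = unname(pref)),
    trial_logits = tibble::tibble(trial_id = trials$trial_id,
                                  eta_pre = eta_pre, eta_post = eta_post)
  )
  list(study = study, truth = truth)
}

# Markov gaze chains for all trials at once; returns a trials x bins
# integer matrix over 1 = TARGET, 2 = DISTRACTOR, 3 = AWAY. The
# post-naming logit switches on at bins starting at or after 367 ms.
simulate_gaze_chains <- function(config, eta_pre, eta_post) {
  span <- config$trial_span_ms
  bin_ms <- config$bin_ms
  n_bins <- floor((span[2] - span[1]) / bin_ms)
  starts <- span[1] + (seq_len(n_bins) - 1) * bin_ms
  post <- starts >= 367
  n_trials <- length(eta_pre)
  p_pre <- plogis(eta_pre)
  p_post <- plogis(eta_post)

  draw_state <- function(p_target) {
    u <- runif(n_trials)
    ifelse(u < config$away_prob, 3L,
           ifelse(runif(n_trials) < p_target, 1L, 2L))
  }
  states <- matrix(0L, n_trials, n_bins)
  states[, 1] <- draw_state(if (post[1]) p_post else p_pre)
  for (k in 2:n_bins) {
    redraw <- runif(n_trials) >= config$stay_prob
    states[, k] <- states[, k - 1]
    if (any(redraw)) {
      p <- if (post[k]) p_post else p_pre
      u <- runif(n_trials)
      u2 <- runif(n_trials)
      new_state <- ifelse(u < config$away_prob, 3L,
                          ifelse(u2 < p, 1L, 2L))
      states[redraw, k] <- new_state[redraw]
    }
  }
  states
}

# Convert state runs to look records on the session clock. AWAY runs are
# uncoded gaps; TARGET/DISTRACTOR map back to LEFT/RIGHT via target side.
states_to_looks <- function(states, trials, config) {
  span <- config$trial_span_ms
  bin_ms <- config$bin_ms
  acc <- list(trial = vector("list", nrow(trials)),
              val = vector("list", nrow(trials)),
              on = vector("list", nrow(trials)),
              off = vector("list", nrow(trials)))
  for (i in seq_len(nrow(trials))) {
    r <- rle(states[i, ])
    keep <- r$values != 3L
    if (!any(keep)) next
    ends <- cumsum(r$lengths)
    starts_bin <- ends - r$lengths
    t0 <- trials$target_onset_ms[i] + span[1]
    acc$trial[[i]] <- rep.int(i, sum(keep))
    acc$val[[i]] <- r$values[keep]
    acc$on[[i]] <- t0 + starts_bin[keep] * bin_ms
    acc$off[[i]] <- t0 + ends[keep] * bin_ms
  }
  idx <- unlist(acc$trial, use.names = FALSE)
  val <- unlist(acc$val, use.names = FALSE)
  side <- trials$target_side[idx]
  other <- ifelse(side == "LEFT", "RIGHT", "LEFT")
  tibble::tibble(
    subject_id = trials$subject_id[idx],
    trial_id = trials$trial_id[idx],
    direction = ifelse(val == 1L, side, other),
    onset_ms = unlist(acc$on, use.names = FALSE),
    offset_ms = unlist(acc$off, use.names = FALSE)
  )
}

#' Score parameter recovery for one simulated replicate
#'
#' @param truth the `truth` element from [simulate_study()].
#' @param glmm a `glmm_result` fitted to the simulated study (phase model).
#' @param score_table optional [aggregate_scores()] result for the same
#'   study.
#' @return list: `beta_true`, `beta_hat`, `beta_error` (logit scale),
#'   `or_true`, `or_hat`, `ci_covers_or`, `item_effect_cor` (fitted vs.
#'   true item intercepts, when the fit has item effects), and — when a
#'   score table is supplied — `mean_score` (grand subject-level mean).
#' @export
recovery_report <- function(truth, glmm, score_table = NULL) {
  stopifnot(inherits(glmm, "glmm_result"))
  beta_true <- truth$config$knowledge_effect
  row <- glmm$fixed[glmm$fixed$term == "phasePOST", , drop = FALSE]
  if (nrow(row) != 1) {
    abort("glmm fit has no phasePOST term", class = "gazelex_stat_error")
  }
  out <- list(
    beta_true = beta_true,
    beta_hat = row$estimate,
    beta_error = row$estimate - beta_true,
    or_true = exp(beta_true),
    or_hat = row$or,
    ci_covers_or = row$or_low <= exp(beta_true) &&
      exp(beta_true) <= row$or_high
  )
  if (glmm$random == "subject_item") {
    re <- lme4::ranef(glmm$model)$word_pair_id
    truth_items <- truth$items[match(rownames(re), truth$items$word_pair_id), ]
    if (nrow(truth_items) != nrow(re) ||
        any(is.na(truth_items$word_pair_id))) {
      abort("item identifiers in fit and truth do not match",
            class = "gazelex_validation_error")
    }
    out$item_effect_cor <- if (sd(truth_items$u_item) == 0 ||
                                 sd(re[["(Intercept)"]]) == 0) {
      NA_real_  # degenerate truth (e.g. null config): correlation undefined
    } else {
      stats::cor(re[["(Intercept)"]], truth_items$u_item)
    }
  }
  if (!is.null(score_table)) {
    out$mean_score <- score_table$grand_subject_mean
  }
  out
}

#' Replicate-level recovery simulation
#'
#' Simulates `n_reps` studies from `config` (seeds derived from
#' `config$seed`), runs each through the standard pipeline (exclusions,
#' phase bin counts, mixed logit fit, optionally difference scores) and
#' summarises recovery of the phase effect.
#'
#' @param config a [sim_config()].
#' @param n_reps number of replicates.
#' @param with_scores also compute pair-score grand means per replicate.
#' @param random random-effect structure passed to [fit_phase_glmm()].
#' @return list: `replicates` (per-replicate tibble), `bias` and `rmse` of
#'   the phase coefficient (logit scale), `or_bias`, `ci_coverage`, and
#'   `mean_score` / `mean_score_se` when requested.
#' @export
recovery_simulation <- function(config, n_reps = 200, with_scores = FALSE,
                                random = c("subject_item", "subject")) {
  random <- match.arg(random)
  seeds <- config$seed + seq_len(n_reps) - 1L
  rows <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    sim <- simulate_study(cfg)
    excl <- classify_study(sim$study)
    counts <- phase_bin_counts(sim$study, excl, bin_ms = config$bin_ms)
    fit <- fit_phase_glmm(counts, random = random)
    st <- if (with_scores) {
      aggregate_scores(pair_scores(sim$study, excl))
    } else {
      NULL
    }
    rep <- recovery_report(sim$truth, fit, st)
    tibble::tibble(
      seed = s, beta_hat = rep$beta_hat, beta_error = rep$beta_error,
      or_hat = rep$or_hat, ci_covers_or = rep$ci_covers_or,
      mean_score = if (with_scores) rep$mean_score else NA_real_
    )
  })
  reps <- dplyr::bind_rows(rows)
  out <- list(
    replicates = reps,
    bias = mean(reps$beta_error),
    rmse = sqrt(mean(reps$beta_error^2)),
    or_bias = mean(reps$or_hat) - exp(config$knowledge_effect),
    ci_coverage = mean(reps$ci_covers_or)
  )
  if (with_scores) {
    out$mean_score <- mean(reps$mean_score)
    out$mean_score_se <- sd(reps$mean_score) / sqrt(n_reps)
  }
  out
}
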