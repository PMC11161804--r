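spec_row <- function(target_side = "LEFT", onset = 1000, crying = FALSE,
                     error = FALSE) {
  trial_manifest(data.frame(
    trial_id = "t01", experiment = "NOUNS", word_pair_id = "wp1",
    image_pair_index = 1, target_word = "wp1_a", target_side = target_side,
    target_onset_ms = onset, crying_flag = crying, error_flag = error
  ), check_design = FALSE)
}

looks_for <- function(direction, onset_ms, offset_ms) {
  look_records(rep("t01", length(onset_ms)), direction, onset_ms, offset_ms)
}

test_that("alignment shifts times and maps directions to gaze roles", {
  lk <- looks_for(direction = "L", onset_ms = 1200, offset_ms = 1500)
  al <- align_trial(spec_row("LEFT"), lk)
  expect_equal(al$looks$role, "TARGET")
  expect_equal(al$looks$onset_ms, 200)
  expect_equal(al$looks$offset_ms, 500)

  al2 <- align_trial(spec_row("RIGHT"), lk)
  expect_equal(al2$looks$role, "DISTRACTOR")
  expect_equal(al2$looks$onset_ms, 200)

  # a look spanning the onset is not split
  lk3 <- looks_for(direction = "L", onset_ms = 800, offset_ms = 1400)
  al3 <- align_trial(spec_row("LEFT"), lk3)
  expect_equal(nrow(al3$looks), 1)
  expect_equal(al3$looks$onset_ms, -200)
  expect_equal(al3$looks$offset_ms, 400)
})

test_that("window summaries clip looks and conserve the window duration", {
  # full-window target look
  al <- align_trial(spec_row(), looks_for(direction = "L",
                                          onset_ms = 1367, offset_ms = 4500))
  s <- summarize_window(al, window_analysis())
  expect_equal(s$target_ms, 3133)
  expect_equal(s$distractor_ms, 0)
  expect_equal(s$away_ms, 0)

  # no looks at all
  empty <- align_trial(spec_row(), looks_for(direction = character(0),
                                             onset_ms = numeric(0),
                                             offset_ms = numeric(0)))
  s0 <- summarize_window(empty, window_analysis())
  expect_equal(s0$away_ms, 3133)

  # clipping: TARGET [0,1000) + DISTRACTOR [1000,2000) against [367,3500)
  al2 <- align_trial(spec_row(), looks_for(
    direction = c("L", "R"), onset_ms = c(1000, 2000),
    offset_ms = c(2000, 3000)
  ))
  s2 <- summarize_window(al2, window_analysis())
  expect_equal(s2$target_ms, 633)
  expect_equal(s2$distractor_ms, 1000)

  # conservation on random fixtures, against a 1 ms brute-force oracle
  withr::with_seed(99, {
    for (rep in 1:20) {
      lk <- random_looks("t01")
      al_r <- align_trial(spec_row(), validate_looks(lk))
      for (w in list(window_prenaming(), window_analysis())) {
        s_r <- summarize_window(al_r, w)
        expect_equal(s_r$target_ms + s_r$distractor_ms + s_r$away_ms,
                     w$end_ms - w$start_ms)
        o <- oracle_window_summary(al_r$looks, w$start_ms, w$end_ms)
        expect_equal(s_r$target_ms, unname(o["target_ms"]))
        expect_equal(s_r$distractor_ms, unname(o["distractor_ms"]))
      }
    }
  })
})

test_that("binning uses majority occupancy with a start-state tie-break", {
  al <- align_trial(spec_row(), looks_for(direction = "L",
                                          onset_ms = 1367, offset_ms = 4500))
  states <- bin_window(al, window_analysis(), 20)
  expect_length(states, 156)  # floor(3133 / 20), trailing partial dropped
  expect_true(all(states == "TARGET"))

  empty <- align_trial(spec_row(), looks_for(direction = character(0),
                                             onset_ms = numeric(0),
                                             offset_ms = numeric(0)))
  expect_true(all(bin_window(empty, window_analysis(), 20) == "AWAY"))
  expect_length(bin_window(empty, window_prenaming(), 20), 18)

  # 10 ms TARGET then 10 ms DISTRACTOR in the first bin: tie goes to the
  # role active at the bin start
  al_tie <- align_trial(spec_row(), looks_for(
    direction = c("L", "R"), onset_ms = c(1367, 1377),
    offset_ms = c(1377, 1387)
  ))
  expect_equal(bin_window(al_tie, window_analysis(), 20)[1], "TARGET")

  expect_error(bin_window(empty, window_prenaming(), 500),
               class = "gazelex_validation_error")
})

test_that("1 ms bins reproduce window durations exactly", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      lk <- random_looks("t01")
      al <- align_trial(spec_row(), validate_looks(lk))
      s <- summarize_window(al, window_analysis())
      states <- bin_window(al, window_analysis(), 1)
      expect_equal(sum(states == "TARGET"), s$target_ms)
      expect_equal(sum(states == "DISTRACTOR"), s$distractor_ms)
      expect_equal(sum(states == "AWAY"), s$away_ms)
    }
  })
})

test_that("vectorised study paths agree with the per-trial reference", {
  sim <- simulate_study(sim_config(n_subjects = 3, seed = 13,
                                   away_prob = 0.3))
  study <- sim$study
  aligned <- align_study(study)
  for (w in list(window_prenaming(), window_analysis())) {
    ref <- summarize_study_window(aligned, w)
    fast <- window_summaries_fast(study, w)
    expect_equal(fast$target_ms, ref$target_ms)
    expect_equal(fast$distractor_ms, ref$distractor_ms)
    expect_equal(fast$away_ms, ref$away_ms)
  }
  counts <- phase_bin_counts(study)
  post <- counts[counts$phase == "POST", ]
  ref_counts <- t(vapply(aligned, function(tr) {
    st <- bin_window(tr, window_analysis(), 20)
    c(sum(st == "TARGET"), sum(st == "DISTRACTOR"))
  }, numeric(2)))
  expect_equal(post$target_bins, unname(ref_counts[post$trial_id, 1]))
  expect_equal(post$distractor_bins, unname(ref_counts[post$trial_id, 2]))
})

test_that("trial exclusion applies every rule that fires, with the exact
           one-third boundary", {
  # 1000 ms of looking in the analysis window: below 3133/3 ms
  st <- timed_study(data.frame(
    target_ms = c(600, rep(2000, 31)), distractor_ms = c(400, rep(500, 31))
  ))
  excl <- classify_study(st)
  expect_true(excl$excluded[1])
  expect_equal(excl$reasons[1], "MIN_LOOKING")
  expect_false(any(excl$excluded[-1]))

  # crying and an absent pre-naming look are both recorded
  st2 <- timed_study(data.frame(
    target_ms = rep(2000, 32), distractor_ms = rep(500, 32),
    skip_prenaming = c(TRUE, rep(FALSE, 31)),
    crying = c(TRUE, rep(FALSE, 31)), error = FALSE
  ))
  excl2 <- classify_study(st2)
  expect_true(excl2$no_prenaming_look[1] && excl2$crying[1])
  expect_equal(excl2$reasons[1], "NO_PRENAMING_LOOK;CRYING")

  # strict inequality at the boundary: 1044.34 ms > 3133/3 is retained
  st3 <- timed_study(data.frame(
    target_ms = c(1044.34, 1044.33, rep(2000, 30)),
    distractor_ms = rep(0, 32)
  ))
  excl3 <- classify_study(st3)
  expect_false(excl3$excluded[1])
  expect_true(excl3$excluded[2])
  expect_equal(excl3$reasons[2], "MIN_LOOKING")

  # agreement with the brute-force oracle on randomized fixtures
  withr::with_seed(7, {
    for (rep in 1:10) {
      lk <- random_looks("t01", n_looks = 6)
      spec <- spec_row(crying = rep %% 2 == 0)
      al <- align_trial(spec, validate_looks(lk))
      got <- classify_trial(spec, al)
      want <- oracle_classify(al$looks, crying = rep %% 2 == 0,
                              error = FALSE)
      expect_equal(got$excluded, any(want))
      expect_equal(
        got$reasons,
        paste(names(want)[want], collapse = ";")
      )
    }
  })
})

test_that("subjects are retained at half the designed trial count", {
  # 16 usable of 32 designed trials: retained (boundary inclusive)
  st <- timed_study(data.frame(
    target_ms = c(rep(0, 16), rep(2000, 16)),
    distractor_ms = c(rep(500, 16), rep(500, 16))
  ))
  excl <- classify_study(st)
  filt <- filter_subjects(st, excl)
  expect_equal(sum(excl$excluded), 16)
  expect_equal(filt$retained, "sA")

  # honorifics subject with 3 usable of 8: excluded
  st2 <- timed_study(data.frame(
    target_ms = c(rep(0, 5), rep(2000, 3)),
    distractor_ms = rep(300, 8)
  ), experiment = "HONORIFICS")
  filt2 <- filter_subjects(st2, classify_study(st2))
  expect_equal(filt2$excluded, "sA")
  expect_equal(filt2$audit$usable_trial_count, 3)
})
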