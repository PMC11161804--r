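ws <- function(target_ms, distractor_ms, away_ms = 0, trial_id = "t") {
  tibble::tibble(trial_id = trial_id, window = "ANALYSIS",
                 target_ms = target_ms, distractor_ms = distractor_ms,
                 away_ms = away_ms)
}

test_that("target proportion excludes away time from the denominator", {
  expect_equal(target_proportion(ws(2000, 1000, 500)), 2 / 3)
  expect_equal(target_proportion(ws(3133, 0, 0)), 1)
  expect_error(target_proportion(ws(0, 0, 3133)),
               class = "gazelex_proportion_error")
})

test_that("the image-pair score subtracts baseline looking to the image", {
  # 0.60 to the image when named, 0.40 to it when its pair-mate is named
  a <- ws(600, 400)   # image is target, p = 0.60
  b <- ws(600, 400)   # pair-mate is target; 0.40 of looking on the image
  expect_equal(image_pair_score(a, b), 0.2)
  # identical looking on both trials gives zero
  expect_equal(image_pair_score(ws(500, 500), ws(500, 500)), 0)
  # designating the other image of the pair gives the same score:
  # swap the roles of the two trials
  expect_equal(image_pair_score(b, a), image_pair_score(a, b))
})

test_that("image-choice symmetry holds to numerical precision on random
           proportions", {
  withr::with_seed(31, {
    for (rep in 1:50) {
      t1 <- ws(runif(1, 1, 3000), runif(1, 1, 3000), runif(1, 0, 500))
      t2 <- ws(runif(1, 1, 3000), runif(1, 1, 3000), runif(1, 0, 500))
      s_img1 <- image_pair_score(t1, t2)
      s_img2 <- image_pair_score(t2, t1)
      expect_lt(abs(s_img1 - s_img2), 1e-12)
      expect_true(s_img1 >= -1 && s_img1 <= 1)
    }
  })
})

test_that("word_pair_score averages defined image-pairs and treats missing
           as a value", {
  expect_equal(word_pair_score(c(0.20, 0.10)),
               list(score = 0.15, n_image_pairs_used = 2L))
  expect_equal(word_pair_score(c(0.20, NA)),
               list(score = 0.20, n_image_pairs_used = 1L))
  none <- word_pair_score(c(NA_real_, NA_real_))
  expect_true(is.na(none$score))
  expect_equal(none$n_image_pairs_used, 0L)
})

test_that("word-pair scores average the complete image-pairs and record n", {
  # build one subject with controlled per-trial proportions
  # wp1/ip1: p = 0.8 and 0.7 -> score 0.5; wp1/ip2: p = 0.6 and 0.5 -> 0.1
  st <- timed_study(data.frame(
    target_ms = c(1600, 1400, 1200, 1500, rep(2000, 28)),
    distractor_ms = c(400, 600, 800, 1500, rep(500, 28))
  ))
  sc <- pair_scores(st)
  wp1 <- sc[sc$word_pair_id == "wp1", ]
  expect_equal(wp1$score, mean(c(0.8 + 0.7 - 1, 0.6 + 0.5 - 1)))
  expect_equal(wp1$n_image_pairs_used, 2)

  # excluding one presentation drops that image-pair but keeps the other
  excl <- classify_study(st)
  excl$excluded[excl$trial_id == st$trials$trial_id[3]] <- TRUE
  sc2 <- pair_scores(st, excl)
  wp1b <- sc2[sc2$word_pair_id == "wp1", ]
  expect_equal(wp1b$score, 0.8 + 0.7 - 1)
  expect_equal(wp1b$n_image_pairs_used, 1)

  # with both image-pairs incomplete the score is missing, not an error
  excl$excluded[excl$trial_id %in% st$trials$trial_id[c(1, 3)]] <- TRUE
  sc3 <- pair_scores(st, excl)
  expect_true(is.na(sc3$score[sc3$word_pair_id == "wp1"]))
  expect_equal(sc3$n_image_pairs_used[sc3$word_pair_id == "wp1"], 0)
})

test_that("aggregation matches an independent group-by oracle", {
  scores <- tibble::tibble(
    subject_id = rep(c("s1", "s2"), each = 3),
    word_pair_id = rep(c("wpA", "wpB", "wpC"), 2),
    score = c(0.1, 0.3, NA, 0.2, -0.1, 0.2),
    n_image_pairs_used = c(2, 2, 0, 1, 2, 2)
  )
  tab <- aggregate_scores(scores)
  expect_equal(tab$item_means$mean_score[tab$item_means$word_pair_id == "wpA"],
               0.15)
  expect_equal(
    tab$subject_means$mean_score[tab$subject_means$subject_id == "s2"],
    mean(c(0.2, -0.1, 0.2))
  )
  expect_equal(setNames(tab$item_means$mean_score,
                        tab$item_means$word_pair_id),
               oracle_item_means(scores))
  expect_equal(setNames(tab$subject_means$mean_score,
                        tab$subject_means$subject_id),
               oracle_subject_means(scores))

  # full synthetic cohort against the same oracle
  sim <- simulate_study(sim_config(n_subjects = 5, seed = 3))
  sc <- pair_scores(sim$study, classify_study(sim$study))
  tab2 <- aggregate_scores(sc)
  expect_equal(setNames(tab2$item_means$mean_score,
                        tab2$item_means$word_pair_id),
               oracle_item_means(sc))
  expect_equal(tab2$grand_item_mean, mean(oracle_item_means(sc)))
})
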