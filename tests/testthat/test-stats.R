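test_that("percentile bootstrap is reproducible and degenerates sensibly", {
  x <- c(0.1, 0.2, 0.05, 0.3, 0.15)
  b1 <- percentile_bootstrap_ci(x, n_reps = 2000, seed = 11)
  b2 <- percentile_bootstrap_ci(x, n_reps = 2000, seed = 11)
  expect_equal(b1$ci_low, b2$ci_low)
  expect_equal(b1$ci_high, b2$ci_high)
  expect_true(b1$ci_low <= b1$estimate && b1$estimate <= b1$ci_high)

  expect_warning(bc <- percentile_bootstrap_ci(rep(0.5, 4), n_reps = 1000,
                                               seed = 1))
  expect_equal(c(bc$ci_low, bc$ci_high), c(0.5, 0.5))
  expect_error(percentile_bootstrap_ci(0.5, n_reps = 1000, seed = 1),
               class = "gazelex_stat_error")
})

test_that("bootstrap CI covers the true mean at roughly the nominal rate
           and narrows as 1/sqrt(n)", {
  withr::with_seed(2024, {
    hits <- 0
    n_rep <- 200
    for (r in seq_len(n_rep)) {
      x <- rnorm(8, mean = 0.12, sd = 0.07)
      b <- percentile_bootstrap_ci(x, n_reps = 1000, seed = r)
      if (b$ci_low <= 0.12 && 0.12 <= b$ci_high) hits <- hits + 1
    }
    # small-sample percentile intervals undercover slightly; allow the
    # usual binomial slack around ~93-95%
    expect_gt(hits / n_rep, 0.85)

    width_at <- function(n) {
      mean(replicate(30, {
        x <- rnorm(n, 0.12, 0.07)
        b <- percentile_bootstrap_ci(x, n_reps = 1000, seed = 1)
        b$ci_high - b$ci_low
      }))
    }
    w8 <- width_at(8)
    w128 <- width_at(128)
    expect_equal(w8 / w128, 4, tolerance = 0.35)
  })
})

test_that("Wilcoxon p-values match their standard conventions", {
  # all-positive sample of 8: most extreme rank sum, p = 2/2^8
  t1 <- wilcoxon_signed_rank(1:8)
  expect_equal(t1$p_value, 2 / 2^8)
  # antisymmetric pair: p = 1
  expect_equal(wilcoxon_signed_rank(c(-0.4, 0.4))$p_value, 1)
  # zeros are dropped
  expect_equal(wilcoxon_signed_rank(c(0, 0, 1:8))$n, 8)
  expect_error(wilcoxon_signed_rank(c(0, 0)), class = "gazelex_stat_error")

  # exact and normal-approximation paths agree closely by n = 30
  withr::with_seed(5, {
    x <- rnorm(30, 0.3, 1)
    p_exact <- suppressWarnings(wilcox.test(x, exact = TRUE)$p.value)
    p_pkg <- wilcoxon_signed_rank(x)$p_value
    expect_lt(abs(p_pkg - p_exact), 0.01)
  })
})

test_that("exact sign test reproduces hand-computed binomial p-values", {
  expect_equal(exact_sign_test(2, 2)$p_value, 0.5)
  expect_equal(exact_sign_test(11, 15)$p_value, oracle_sign_p(11, 15),
               tolerance = 1e-12)
  expect_equal(round(exact_sign_test(11, 15)$p_value, 3), 0.118)
  expect_equal(exact_sign_test(8, 8)$p_value, 2 * (1 / 2)^8)
  expect_error(exact_sign_test(0, 0), class = "gazelex_stat_error")
})

test_that("one-sample Cohen's d is mean over sample SD", {
  expect_equal(one_sample_cohens_d(c(0.08, 0.18)), 0.13 / sd(c(0.08, 0.18)))
  expect_equal(one_sample_cohens_d(c(0.08, 0.18)), 1.838, tolerance = 1e-3)
  expect_equal(one_sample_cohens_d(c(-1, 0, 1)), 0)
  x <- c(0.05, 0.2, 0.11, 0.4)
  expect_equal(one_sample_cohens_d(3 * x), one_sample_cohens_d(x))
  expect_error(one_sample_cohens_d(rep(0.2, 5)),
               class = "gazelex_stat_error")
})

test_that("Kendall tau counts concordant pairs and is symmetric", {
  expect_equal(kendall_tau(1:6, 2 * (1:6))$statistic, 1)
  t2 <- kendall_tau(c(1, 2, 3), c(1, 3, 2))
  expect_equal(t2$statistic, 1 / 3)
  x <- c(5.2, 7.1, 9.9, 11.3, 14.8)
  y <- c(0.02, -0.05, 0.2, 0.11, 0.4)
  expect_equal(kendall_tau(x, y)$statistic, kendall_tau(y, x)$statistic)
  expect_equal(kendall_tau(x, y)$p_value, kendall_tau(y, x)$p_value)
  expect_error(kendall_tau(rep(1, 5), 1:5), class = "gazelex_stat_error")
})

test_that("intercept LMM recovers the grand mean when subjects are
           homogeneous and reports a valid LRT", {
  # balanced data, zero subject variance: intercept is the grand mean
  d <- tibble::tibble(
    subject_id = rep(sprintf("s%d", 1:6), each = 4),
    word_pair_id = rep(sprintf("wp%d", 1:4), 6),
    score = rep(c(0.1, 0.2, 0.05, 0.25), 6)
  )
  fit <- fit_intercept_lmm(d)
  expect_equal(fit$intercept, mean(d$score), tolerance = 1e-8)
  expect_true(fit$lrt_chisq >= 0)
  expect_equal(fit$lrt_df, 1)

  # null simulation: estimate within 3 SEs of zero
  withr::with_seed(77, {
    d2 <- tibble::tibble(
      subject_id = rep(sprintf("s%d", 1:21), each = 8),
      score = rnorm(21 * 8, 0, 0.15) + rep(rnorm(21, 0, 0.1), each = 8)
    )
    fit2 <- fit_intercept_lmm(d2)
    se <- fit2$intercept / fit2$t_value
    expect_lt(abs(fit2$intercept), 3 * abs(se))
    expect_true(fit2$df <= nrow(d2) - 1)
  })
})

test_that("the intercept LMM recovers a known mean across simulated
           cohorts", {
  withr::with_seed(42, {
    covered <- 0
    n_rep <- 40
    for (r in seq_len(n_rep)) {
      d <- tibble::tibble(
        subject_id = rep(sprintf("s%d", 1:21), each = 8),
        score = 0.12 + rep(rnorm(21, 0, sqrt(0.02)), each = 8) +
          rnorm(168, 0, sqrt(0.01))
      )
      fit <- fit_intercept_lmm(d)
      if (fit$intercept_ci[1] <= 0.12 && 0.12 <= fit$intercept_ci[2]) {
        covered <- covered + 1
      }
    }
    expect_gt(covered / n_rep, 0.85)
  })
})

test_that("the degenerate single-subject mixed logit matches plain
           logistic regression", {
  withr::with_seed(8, {
    d <- tibble::tibble(
      subject_id = "s1",
      trial_id = sprintf("t%02d", 1:32),
      word_pair_id = rep(sprintf("wp%d", 1:8), 4),
      phase = factor(rep(c("PRE", "POST"), 16), levels = c("PRE", "POST")),
      target_bins = rpois(32, 40) + 1L,
      distractor_bins = rpois(32, 30) + 1L,
      age_months = 10
    )
    fit <- fit_phase_glmm(d, random = "subject")
    ref <- glm(cbind(target_bins, distractor_bins) ~ phase, data = d,
               family = binomial())
    expect_equal(fit$fixed$estimate, unname(coef(ref)), tolerance = 1e-4)
    expect_equal(fit$fixed$or, exp(unname(coef(ref))), tolerance = 1e-4)
    expect_equal(fit$fixed$wald_chisq, fit$fixed$z^2)
  })
})

test_that("nested model comparison has the right degrees of freedom and a
           non-negative statistic", {
  sim <- simulate_study(sim_config(n_subjects = 6, seed = 21))
  counts <- phase_bin_counts(sim$study, classify_study(sim$study))
  m0 <- fit_phase_glmm(counts, random = "subject_item")
  m1 <- fit_phase_glmm(counts, random = "subject_item", age = TRUE)
  cmp <- compare_models(m0, m1)
  expect_equal(cmp$df, 2)
  expect_gte(cmp$chisq, 0)
  expect_equal(compare_models(m0, m0)$chisq, 0)
  expect_error(compare_models(m1, m0), class = "gazelex_stat_error")
})
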