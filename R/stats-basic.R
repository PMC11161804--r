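#' Percentile bootstrap CI for a mean
#'
#' Resamples the supplied units (typically subjects — the exchangeable unit
#' in this design — or, for an item mean, the subjects contributing to that
#' item) with replacement and takes the 2.5/97.5 percentiles of the
#' resampled statistic. Reproducible under a fixed seed, which is recorded
#' in the result.
#'
#' @param values numeric vector, one value per resampling unit.
#' @param n_reps number of bootstrap replicates (default 10000).
#' @param seed integer seed.
#' @param statistic function of a numeric vector (default `mean`).
#' @param level confidence level.
#' @param resampling_unit label recorded in the result (`"SUBJECT"` or
#'   `"ITEM"`).
#' @return list of class `bootstrap_result`: `estimate`, `ci_low`,
#'   `ci_high`, `level`, `n_reps`, `seed`, `resampling_unit`.
#' @export
percentile_bootstrap_ci <- function(values, n_reps = 10000, seed = 1,
                                    statistic = mean, level = 0.95,
                                    resampling_unit = "SUBJECT") {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) {
    abort("bootstrap needs at least 2 units", class = "gazelex_stat_error")
  }
  if (n_reps < 1000) {
    abort("use at least 1000 bootstrap replicates",
          class = "gazelex_stat_error")
  }
  if (length(unique(values)) == 1) {
    warn("all values identical; bootstrap interval is degenerate")
  }
  est <- statistic(values)
  stats_boot <- withr::with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_reps, replace = TRUE), nrow = n_reps)
    apply(idx, 1, function(i) statistic(values[i]))
  })
  qs <- quantile(stats_boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE, type = 7)
  structure(
    list(estimate = est, ci_low = qs[1], ci_high = qs[2], level = level,
         n_reps = n_reps, seed = seed, resampling_unit = resampling_unit),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("M = %.3f, %d%% bootstrapped CI = [%.3f, %.3f] (%d reps, %s resampling)\n",
              x$estimate, round(100 * x$level), x$ci_low, x$ci_high,
              x$n_reps, tolower(x$resampling_unit)))
  invisible(x)
}

#' Two-sided Wilcoxon signed-rank test against a null centre
#'
#' Zeros (values equal to the centre) are dropped, per the signed-rank
#' convention. The p-value is exact (signed-rank distribution) for
#' n <= 25 without ties in the absolute deviations; with ties it is an
#' exact sign-flip enumeration up to n = 16; otherwise the normal
#' approximation with continuity and tie correction is used.
#'
#' @param values numeric vector.
#' @param null_center the hypothesised centre (default 0).
#' @return list of class `gaze_test`: `statistic` (V), `p_value`, `method`,
#'   `sidedness`, `n` (non-zero deviations).
#' @export
wilcoxon_signed_rank <- function(values, null_center = 0) {
  dev <- values[!is.na(values)] - null_center
  dev <- dev[dev != 0]
  n <- length(dev)
  if (n < 2) {
    abort("Wilcoxon test needs at least 2 non-zero deviations",
          class = "gazelex_stat_error")
  }
  r <- rank(abs(dev))
  v <- sum(r[dev > 0])
  has_ties <- anyDuplicated(abs(dev)) > 0
  if (!has_ties && n <= 25) {
    p <- suppressWarnings(
      wilcox.test(dev, mu = 0, exact = TRUE)$p.value
    )
    method <- "WILCOXON_EXACT"
  } else if (has_ties && n <= 16) {
    p <- signflip_p(dev)
    method <- "WILCOXON_SIGNFLIP"
  } else {
    p <- suppressWarnings(
      wilcox.test(dev, mu = 0, exact = FALSE, correct = TRUE)$p.value
    )
    method <- "WILCOXON_NORMAL"
  }
  structure(
    list(statistic = v, p_value = p, method = method,
         sidedness = "two.sided", n = n),
    class = "gaze_test"
  )
}

# Exact two-sided sign-flip p for the signed-rank statistic with ties:
# enumerate all 2^n sign assignments of the (tied) ranks and count
# rank-sums at least as far from the mean as observed.
signflip_p <- function(dev) {
  r <- rank(abs(dev))
  v_obs <- sum(r[dev > 0])
  n <- length(r)
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9)
}

#' Exact two-sided sign (binomial) test
#'
#' Tests whether `n_positive` of `n_total` positive scores exceeds a
#' fair-coin null. The two-sided p is the sum of the probabilities of all
#' outcomes no more likely than the observed one (the standard exact
#' binomial convention). Zero scores must have been dropped upstream.
#'
#' @param n_positive,n_total non-negative integers.
#' @return a `gaze_test` with `statistic = n_positive`.
#' @export
exact_sign_test <- function(n_positive, n_total) {
  if (n_total == 0) {
    abort("sign test needs at least one non-zero score",
          class = "gazelex_stat_error")
  }
  stopifnot(n_positive >= 0, n_positive <= n_total)
  p <- binom.test(n_positive, n_total, p = 0.5,
                  alternative = "two.sided")$p.value
  structure(
    list(statistic = n_positive, p_value = p, method = "EXACT_BINOMIAL",
         sidedness = "two.sided", n = n_total),
    class = "gaze_test"
  )
}

#' One-sample Cohen's d
#'
#' Mean over sample standard deviation (n - 1 denominator), the
#' descriptive effect size conventionally attached to one-sample tests of
#' difference scores against zero.
#'
#' @param values numeric vector.
#' @return a single number.
#' @export
one_sample_cohens_d <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    abort("Cohen's d needs at least 2 values", class = "gazelex_stat_error")
  }
  s <- sd(values)
  if (s == 0) {
    abort("Cohen's d undefined for zero spread", class = "gazelex_stat_error")
  }
  mean(values) / s
}

#' Cohen's d from a logit-scale coefficient
#'
#' The standard conversion d = log(OR) * sqrt(3) / pi, treating the
#' logistic residual as the standardiser.
#'
#' @param log_or coefficient on the logit scale.
#' @return a single number.
#' @export
logit_cohens_d <- function(log_or) log_or * sqrt(3) / pi

#' Kendall rank correlation (tau-b) with two-sided p
#'
#' Exact p for small untied samples (n <= 10), otherwise the usual normal
#' approximation (tie-corrected).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return a `gaze_test` with `statistic` = tau.
#' @export
kendall_tau <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || length(x) != length(y)) {
    abort("Kendall tau needs equal-length vectors with >= 3 pairs",
          class = "gazelex_stat_error")
  }
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    abort("Kendall tau undefined for a constant vector",
          class = "gazelex_stat_error")
  }
  ct <- suppressWarnings(
    cor.test(x, y, method = "kendall", alternative = "two.sided",
             exact = length(x) <= 10 && !anyDuplicated(x) &&
               !anyDuplicated(y))
  )
  structure(
    list(statistic = unname(ct$estimate), p_value = ct$p.value,
         method = "KENDALL", sidedness = "two.sided", n = length(x)),
    class = "gaze_test"
  )
}

#' @export
print.gaze_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, P = %.4g (n = %d, %s)\n",
              x$method, x$statistic, x$p_value, x$n, x$sidedness))
  invisible(x)
}
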