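#' Random-intercept linear mixed model for difference scores
#'
#' Fits `score ~ 1 + (1 | subject)` by REML, asking whether the population
#' mean difference score is positive while letting subjects vary around it.
#' The t test of the intercept uses Satterthwaite degrees of freedom; the
#' likelihood-ratio test of the intercept refits the full and the
#' zero-intercept null model by maximum likelihood.
#'
#' @param scores [pair_scores()] rows (missing scores dropped).
#' @param ci_method `"wald"` (default) or `"profile"` for the intercept CI.
#' @return list of class `lmm_result`: `intercept`, `intercept_ci`,
#'   `t_value`, `df` (Satterthwaite), `p_value`, `lrt_chisq`, `lrt_df`,
#'   `lrt_p`, `variance_components` (subject, residual), `cohens_d`
#'   (intercept / total SD), `n_subjects`, `n_scores`, `model`.
#' @export
fit_intercept_lmm <- function(scores, ci_method = c("wald", "profile")) {
  ci_method <- match.arg(ci_method)
  d <- scores[!is.na(scores$score), , drop = FALSE]
  if (dplyr::n_distinct(d$subject_id) < 2) {
    abort("intercept LMM needs scores from at least 2 subjects",
          class = "gazelex_stat_error")
  }
  fit <- tryCatch(
    lmerTest::lmer(score ~ 1 + (1 | subject_id), data = d, REML = TRUE),
    error = function(e) {
      abort(paste0("LMM failed to converge: ", conditionMessage(e)),
            class = "gazelex_convergence_error")
    }
  )
  co <- coef(summary(fit))
  ci <- if (ci_method == "wald") {
    suppressMessages(confint(fit, parm = "(Intercept)", method = "Wald"))
  } else {
    suppressMessages(confint(fit, parm = "(Intercept)", method = "profile"))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_subject <- vc$vcov[vc$grp == "subject_id"]
  var_resid <- vc$vcov[vc$grp == "Residual"]

  full_ml <- lme4::lmer(score ~ 1 + (1 | subject_id), data = d, REML = FALSE)
  null_ml <- lme4::lmer(score ~ 0 + (1 | subject_id), data = d, REML = FALSE)
  lrt_chisq <- max(0, 2 * (as.numeric(logLik(full_ml)) -
                             as.numeric(logLik(null_ml))))
  lrt_p <- pchisq(lrt_chisq, df = 1, lower.tail = FALSE)

  structure(
    list(
      intercept = unname(co[1, "Estimate"]),
      intercept_ci = c(ci[1, 1], ci[1, 2]),
      t_value = unname(co[1, "t value"]),
      df = unname(co[1, "df"]),
      p_value = unname(co[1, "Pr(>|t|)"]),
      lrt_chisq = lrt_chisq, lrt_df = 1L, lrt_p = lrt_p,
      variance_components = c(subject = var_subject, residual = var_resid),
      cohens_d = unname(co[1, "Estimate"]) / sqrt(var_subject + var_resid),
      n_subjects = dplyr::n_distinct(d$subject_id),
      n_scores = nrow(d),
      model = fit
    ),
    class = "lmm_result"
  )
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf(
    "b0 = %.3f, 95%% CI = [%.3f, %.3f]; t(%.2f) = %.2f, P = %.3g; LRT chi2(1) = %.2f, P = %.3g\n",
    x$intercept, x$intercept_ci[1], x$intercept_ci[2], x$df, x$t_value,
    x$p_value, x$lrt_chisq, x$lrt_p
  ))
  invisible(x)
}

#' Pre/post-naming binomial mixed logit model
#'
#' Models, per trial and phase, the number of 20 ms gaze bins on the target
#' vs. on the distractor as a binomial response on the logit scale, with
#' trial phase (reference `PRE`) as a fixed effect and random intercepts
#' for subject and (optionally) item. The extended model adds standardised
#' age and its interaction with phase. Fitting is by Laplace approximation
#' to the marginal likelihood (`lme4::glmer`, `nAGQ = 1`).
#'
#' The exponentiated phase coefficient is the phase odds ratio: the
#' multiplicative change in the odds that a gaze bin is on-target from the
#' pre-naming to the post-naming phase.
#'
#' @param counts [phase_bin_counts()] output. Rows with no informative bins
#'   (`target_bins + distractor_bins == 0`) are dropped.
#' @param random `"subject_item"` (nouns design) or `"subject"` only
#'   (honorifics design).
#' @param age include age and phase-by-age terms.
#' @param standardize_age z-score age before it enters the model (the
#'   default; set `FALSE` for raw months).
#' @return list of class `glmm_result`: `fixed` (term, estimate, se, z,
#'   wald_chisq, p, or, or_low, or_high, cohens_d), `varcomp`, `loglik`,
#'   `n_obs`, `converged`, `model`.
#' @export
fit_phase_glmm <- function(counts, random = c("subject_item", "subject"),
                           age = FALSE, standardize_age = TRUE) {
  random <- match.arg(random)
  d <- counts[counts$target_bins + counts$distractor_bins > 0, , drop = FALSE]
  d$phase <- factor(as.character(d$phase), levels = c("PRE", "POST"))
  fixed <- if (age) {
    d$age_c <- if (standardize_age) as.numeric(scale(d$age_months)) else
      d$age_months
    "phase * age_c"
  } else {
    "phase"
  }
  rand <- if (random == "subject_item") {
    "(1 | subject_id) + (1 | word_pair_id)"
  } else {
    "(1 | subject_id)"
  }
  form <- as.formula(paste(
    "cbind(target_bins, distractor_bins) ~", fixed, "+", rand
  ))
  ctrl <- lme4::glmerControl(check.conv.singular = "ignore",
                             check.nlev.gtr.1 = "ignore")
  fit <- suppressMessages(lme4::glmer(
    form, data = d, family = stats::binomial(), nAGQ = 1, control = ctrl
  ))
  if (separation_suspected(fit)) {
    warn(paste0("possible separation (extreme fitted logits); refitting ",
                "with Haldane-style 0.5 pseudo-count smoothing"))
    d2 <- d
    d2$target_bins <- d2$target_bins + 0.5
    d2$distractor_bins <- d2$distractor_bins + 0.5
    fit <- suppressWarnings(suppressMessages(lme4::glmer(
      form, data = d2, family = stats::binomial(), nAGQ = 1,
      control = lme4::glmerControl(check.conv.singular = "ignore")
    )))
  }
  co <- coef(summary(fit))
  est <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  fixed_tbl <- tibble::tibble(
    term = rownames(co),
    estimate = unname(est),
    se = unname(se),
    z = unname(est / se),
    wald_chisq = unname((est / se)^2),
    p = unname(2 * pnorm(-abs(est / se))),
    or = exp(unname(est)),
    or_low = exp(unname(est - 1.96 * se)),
    or_high = exp(unname(est + 1.96 * se)),
    cohens_d = logit_cohens_d(unname(est))
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  msgs <- fit@optinfo$conv$lme4$messages
  structure(
    list(
      fixed = fixed_tbl,
      varcomp = setNames(vc$vcov, vc$grp),
      loglik = as.numeric(logLik(fit)),
      n_obs = nrow(d),
      converged = is.null(msgs),
      convergence_messages = msgs,
      random = random, age = age,
      model = fit
    ),
    class = "glmm_result"
  )
}

separation_suspected <- function(fit) {
  any(abs(lme4::fixef(fit)) > 10)
}

#' @export
print.glmm_result <- function(x, ...) {
  cat(sprintf("binomial mixed logit (%s random intercepts%s), logLik = %.1f\n",
              gsub("_", "+", x$random), if (x$age) " + age" else "",
              x$loglik))
  print(as.data.frame(x$fixed), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Likelihood-ratio comparison of nested mixed logit fits
#'
#' @param null,full `glmm_result` objects fitted to the same observations,
#'   `null` nested in `full`.
#' @return list: `chisq`, `df`, `p_value`.
#' @export
compare_models <- function(null, full) {
  stopifnot(inherits(null, "glmm_result"), inherits(full, "glmm_result"))
  df_null <- length(coef(summary(null$model))[, 1]) + length(null$varcomp)
  df_full <- length(coef(summary(full$model))[, 1]) + length(full$varcomp)
  if (null$n_obs != full$n_obs || df_full < df_null) {
    abort("models are not nested on identical data",
          class = "gazelex_stat_error")
  }
  chisq <- max(0, 2 * (full$loglik - null$loglik))
  df <- df_full - df_null
  list(chisq = chisq, df = df,
       p_value = pchisq(chisq, df = df, lower.tail = FALSE))
}

#' Model coefficient table in SI-style shape
#'
#' @param x an `lmm_result` or `glmm_result`.
#' @return tibble: term, estimate, SE, statistic, df, p, OR, CI bounds.
#' @export
model_table <- function(x) {
  if (inherits(x, "lmm_result")) {
    tibble::tibble(
      term = "(Intercept)", estimate = x$intercept,
      se = x$intercept / x$t_value, statistic = x$t_value, df = x$df,
      p = x$p_value, or = NA_real_,
      ci_low = x$intercept_ci[1], ci_high = x$intercept_ci[2]
    )
  } else if (inherits(x, "glmm_result")) {
    tibble::tibble(
      term = x$fixed$term, estimate = x$fixed$estimate, se = x$fixed$se,
      statistic = x$fixed$z, df = NA_real_, p = x$fixed$p, or = x$fixed$or,
      ci_low = x$fixed$or_low, ci_high = x$fixed$or_high
    )
  } else {
    abort("model_table expects an lmm_result or glmm_result")
  }
}
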