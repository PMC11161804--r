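#' Proportion-looking timecourse
#'
#' At each 33 ms interval of the plot range, every usable trial contributes
#' its gaze state (majority-rule, as in [bin_window()]); the curve is the
#' pooled proportion of on-target contributions out of contributions to
#' either image, with a percentile bootstrap over subjects for the CI.
#' Intervals where nobody looks at either image have an undefined
#' proportion (`NA`).
#'
#' @param study a `gaze_study`.
#' @param exclusions [classify_study()] output (`NULL` keeps all trials).
#' @param grid_ms interval width (default 33 ms, i.e. two 60 FPS video
#'   frames).
#' @param range_ms plot range relative to target onset.
#' @param n_reps bootstrap replicates for the interval CIs.
#' @param seed bootstrap seed.
#' @param subject_first average within subject before pooling instead of
#'   pooling trial contributions directly.
#' @return tibble: `t_ms` (interval midpoint), `n_on_target`,
#'   `n_on_either`, `proportion`, `ci_low`, `ci_high`.
#' @export
proportion_curve <- function(study, exclusions = NULL, grid_ms = 33,
                             range_ms = c(-1000, 3500), n_reps = 1000,
                             seed = 1, subject_first = FALSE) {
  window <- window_plot(range_ms)
  n_bins <- floor(window_duration(window) / grid_ms)
  if (n_bins < 1) {
    abort("empty timecourse grid", class = "gazelex_validation_error")
  }
  aligned <- align_study(study)
  if (!is.null(exclusions)) {
    keep <- exclusions$trial_id[!exclusions$excluded]
    aligned <- aligned[names(aligned) %in% keep]
  }
  if (length(aligned) == 0) {
    abort("no usable trials for the timecourse",
          class = "gazelex_validation_error")
  }
  subj <- vapply(aligned, function(a) a$spec$subject_id, character(1))
  states <- vapply(aligned, bin_window, character(n_bins),
                   window = window, bin_ms = grid_ms)
  # states: n_bins x n_trials
  subj_ids <- unique(subj)
  tgt <- matrix(0, n_bins, length(subj_ids),
                dimnames = list(NULL, subj_ids))
  eth <- tgt
  for (s in subj_ids) {
    cols <- which(subj == s)
    tgt[, s] <- rowSums(states[, cols, drop = FALSE] == "TARGET")
    eth[, s] <- tgt[, s] +
      rowSums(states[, cols, drop = FALSE] == "DISTRACTOR")
  }
  pool <- function(t_mat, e_mat) {
    if (subject_first) {
      p <- t_mat / e_mat
      rowMeans(p, na.rm = TRUE)
    } else {
      rowSums(t_mat) / rowSums(e_mat)
    }
  }
  prop <- pool(tgt, eth)
  cis <- withr::with_seed(seed, {
    reps <- replicate(n_reps, {
      pick <- sample.int(length(subj_ids), replace = TRUE)
      pool(tgt[, pick, drop = FALSE], eth[, pick, drop = FALSE])
    })
    apply(reps, 1, quantile, probs = c(0.025, 0.975), na.rm = TRUE,
          names = FALSE)
  })
  tibble::tibble(
    t_ms = window$start_ms + (seq_len(n_bins) - 0.5) * grid_ms,
    n_on_target = rowSums(tgt),
    n_on_either = rowSums(eth),
    proportion = prop,
    ci_low = cis[1, ],
    ci_high = cis[2, ]
  )
}

#' Weighted local-regression smooth of a timecourse
#'
#' Local quadratic regression of the proportion on time, weighted by the
#' number of contributions to either image in each interval (so sparsely
#' populated intervals pull the curve less). Zero-weight and undefined
#' intervals are ignored by the fit; predictions are returned on the full
#' grid.
#'
#' @param points [proportion_curve()] output.
#' @param span loess span (default 0.25).
#' @param degree local polynomial degree (default 2).
#' @return `points` with a `smoothed` column added.
#' @export
smooth_curve <- function(points, span = 0.25, degree = 2) {
  use <- !is.na(points$proportion) & points$n_on_either > 0
  if (sum(use) < 10) {
    abort("need at least 10 populated intervals to smooth",
          class = "gazelex_stat_error")
  }
  fit <- tryCatch(
    loess(proportion ~ t_ms, data = points[use, , drop = FALSE],
          weights = points$n_on_either[use], span = span, degree = degree,
          family = "gaussian"),
    error = function(e) {
      abort(paste0("loess failed (span too small?): ", conditionMessage(e)),
            class = "gazelex_stat_error")
    }
  )
  points$smoothed <- unname(predict(fit, newdata = points))
  points
}

#' Plot a timecourse in the style of a looking-while-listening figure
#'
#' Points with bootstrap error bars, the loess overlay, a vertical line at
#' target-word onset and the shaded analysis window.
#'
#' @param curves named list of smoothed curves (one per experiment), or a
#'   single curve tibble.
#' @param analysis the analysis window to shade.
#' @return a ggplot object.
#' @export
plot_timecourse <- function(curves, analysis = window_analysis()) {
  if (is.data.frame(curves)) curves <- list(study = curves)
  df <- dplyr::bind_rows(curves, .id = "experiment")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ms, y = .data$proportion,
                                        colour = .data$experiment)) +
    ggplot2::annotate("rect", xmin = analysis$start_ms,
                      xmax = analysis$end_ms, ymin = -Inf, ymax = Inf,
                      alpha = 0.12) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, colour = "red") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           alpha = 0.3, width = 0) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(x = "Time from target-word onset (ms)",
                  y = "Proportion looking to target") +
    ggplot2::theme_minimal()
  if ("smoothed" %in% names(df)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$smoothed),
                                linewidth = 1, na.rm = TRUE)
  }
  p
}
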