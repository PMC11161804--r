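#!/usr/bin/env Rscript
# The proportion-looking timecourse: at every 33 ms interval, the share of
# usable-trial gaze on the target out of gaze on either image, with
# subject-resampled bootstrap CIs and a weighted loess overlay. Writes the
# curve CSVs and a two-experiment figure.

suppressPackageStartupMessages(library(gazelex))

curves <- list()
for (exp_name in c("nouns", "honorifics")) {
  study <- suppressWarnings(read_study(file.path("results/data", exp_name)))
  excl <- classify_study(study)
  curve <- proportion_curve(study, excl, n_reps = 1000, seed = 17)
  curve <- smooth_curve(curve)
  readr::write_csv(curve, file.path("results", exp_name, "timecourse.csv"))
  curves[[exp_name]] <- curve
  post <- curve$t_ms >= 367 & curve$t_ms < 3500
  cat(sprintf("[%s] mean post-naming proportion on target: %.3f (pre: %.3f)\n",
              exp_name,
              weighted.mean(curve$proportion[post], curve$n_on_either[post]),
              weighted.mean(curve$proportion[curve$t_ms < 367 &
                                               curve$t_ms >= 0],
                            curve$n_on_either[curve$t_ms < 367 &
                                                curve$t_ms >= 0])))
}
fig <- plot_timecourse(curves)
ggplot2::ggsave("results/timecourse.png", fig, width = 8, height = 4.5,
                dpi = 150)
cat("Figure written to results/timecourse.png\n")
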