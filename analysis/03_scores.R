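#!/usr/bin/env Rscript
# Pair-based baseline-corrected difference scores with their inferential
# battery: bootstrap CIs (subjects resampled), Wilcoxon signed-rank and
# exact sign tests, Cohen's d, and the Kendall correlation of subject
# means with age.

suppressPackageStartupMessages(library(gazelex))

for (exp_name in c("nouns", "honorifics")) {
  study <- suppressWarnings(read_study(file.path("results/data", exp_name)))
  excl <- classify_study(study)
  scores <- pair_scores(study, excl)
  tab <- aggregate_scores(scores)
  write_score_table(tab, file.path("results", exp_name))

  boot_subj <- percentile_bootstrap_ci(
    tab$subject_means$mean_score, n_reps = 10000, seed = 11
  )
  wil <- wilcoxon_signed_rank(tab$item_means$mean_score)
  sign <- exact_sign_test(sum(tab$item_means$mean_score > 0),
                          sum(tab$item_means$mean_score != 0))
  ages <- study$subjects$age_months[
    match(tab$subject_means$subject_id, study$subjects$subject_id)
  ]
  tau <- kendall_tau(tab$subject_means$mean_score, ages)

  cat(sprintf("[%s] item grand mean %.3f (%d/%d pairs positive); subject grand mean %.3f\n",
              exp_name, tab$grand_item_mean,
              sum(tab$item_means$mean_score > 0), nrow(tab$item_means),
              tab$grand_subject_mean))
  cat(sprintf("  subject-mean 95%% bootstrap CI [%.3f, %.3f]; Wilcoxon P = %.3g; sign test P = %.3g\n",
              boot_subj$ci_low, boot_subj$ci_high, wil$p_value,
              sign$p_value))
  cat(sprintf("  Cohen's d (items) = %.2f; Kendall tau with age = %.2f (P = %.2f)\n",
              one_sample_cohens_d(tab$item_means$mean_score),
              tau$statistic, tau$p_value))
}
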