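#!/usr/bin/env Rscript
# Mixed-effects models: the random-intercept LMM of difference scores and
# the pre/post-naming binomial mixed logit models (phase only, then phase
# by standardised age) with their likelihood-ratio comparison.

suppressPackageStartupMessages({
  library(gazelex)
  library(dplyr)
})

for (exp_name in c("nouns", "honorifics")) {
  study <- suppressWarnings(read_study(file.path("results/data", exp_name)))
  excl <- classify_study(study)

  lmm <- fit_intercept_lmm(pair_scores(study, excl))
  cat(sprintf("[%s] score LMM: ", exp_name)); print(lmm)

  random <- if (exp_name == "nouns") "subject_item" else "subject"
  counts <- phase_bin_counts(study, excl)
  m_phase <- fit_phase_glmm(counts, random = random)
  m_age <- fit_phase_glmm(counts, random = random, age = TRUE)
  cmp <- compare_models(m_phase, m_age)

  print(m_phase)
  cat(sprintf("  phase+age improves fit: chi2(%d) = %.2f, P = %.3g\n",
              cmp$df, cmp$chisq, cmp$p_value))

  tables <- bind_rows(
    mutate(model_table(lmm), model = "score_lmm", .before = 1),
    mutate(model_table(m_phase), model = "glmm_phase", .before = 1),
    mutate(model_table(m_age), model = "glmm_phase_age", .before = 1)
  )
  readr::write_csv(tables, file.path("results", exp_name,
                                     "model_tables.csv"))
}
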