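#!/usr/bin/env Rscript
# Apply the trial- and subject-level exclusion rules to the simulated
# cohorts and write the audit trail. Reports how many trials each rule
# caught (rules frequently co-occur) and whether any subject fell below
# half of the designed trial count.

suppressPackageStartupMessages(library(gazelex))

for (exp_dir in c("nouns", "honorifics")) {
  study <- suppressWarnings(read_study(file.path("results/data", exp_dir)))
  excl <- classify_study(study)
  filt <- filter_subjects(study, excl)
  write_exclusion_audit(excl, filt, file.path("results", exp_dir))
  cat(sprintf(
    "[%s] %d/%d trials excluded (no prenaming look %d, crying %d, minimum looking %d, adult error %d); %d/%d subjects retained\n",
    exp_dir, sum(excl$excluded), nrow(excl),
    sum(excl$no_prenaming_look), sum(excl$crying), sum(excl$min_looking),
    sum(excl$adult_error),
    length(filt$retained), nrow(study$subjects)
  ))
}
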