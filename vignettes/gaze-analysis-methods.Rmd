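---
title: "Methods: gaze-based word recognition from interval-coded looking data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze-based word recognition from interval-coded looking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The paradigm and the measurement problem

In a looking-while-listening (language-guided-looking) experiment, an
infant sees two pictures while a caregiver names one of them. If the
infant knows the word, gaze should shift toward the named picture
(the *target*) and away from its pair-mate (the *distractor*). The raw
data are interval-coded gaze annotations from manually coded video: one
record per visible look, with a direction (`LEFT`, `RIGHT`, `AWAY`) and
half-open onset/offset times in milliseconds on the session clock.
Uncoded gaps are treated as `AWAY`, because manual coders annotate
visible fixations only; 60 FPS video cannot resolve gaze below roughly
17 ms, so all times are integer-friendly milliseconds.

Two windows, both relative to target-word onset, organise every
analysis:

* the **pre-naming window** `[0, 367)` ms — 367 ms is the conventional
  allowance for infant saccade-programming latency, so looking in this
  window cannot yet reflect the word;
* the **analysis window** `[367, 3500)` ms, where word-driven looking is
  scored.

Windows are half-open, `[start, end)`, and every summary conserves
duration exactly: target + distractor + away time equals the window
length for every trial (uncoded time is absorbed into away).

## Trial and subject exclusion

A trial is dropped when any of four rules fires, and all firing rules
are recorded (they frequently co-occur):

1. no look to either display during the pre-naming window;
2. the infant was flagged as actively crying;
3. looking to the two displays during the analysis window totals
   strictly less than one third of it — the threshold is kept as the
   exact rational 3133/3 ms, never pre-rounded, and the comparison is a
   strict `<`, so a trial at exactly one third survives;
4. caregiver or experimenter error.

A subject is retained when they contribute usable data on at least half
of the *designed* trial count (32 for the nouns design, 8 for the
honorifics design) — the denominator is the design, not the attended
trials, matching the "half of all test trials" convention. Both rules
are audited: the pipeline writes per-trial reasons and per-subject
tallies so that every excluded observation is accounted for.

Two boundary interpretations were genuinely open and are resolved as
follows. A look that begins before word onset and continues into the
pre-naming window counts toward the pre-naming check, because it
overlaps the window. And the one-third rule uses looking to *either*
display, as does the pre-naming check.

## The pair-based difference score

For one image-pair presented twice (each image serving once as target),
the score is the proportion of looking directed to a designated image
when it was named minus the proportion directed to the same image when
its pair-mate was named. Proportions use looking to either image as the
denominator; away time is excluded. Under that convention the score
equals `p1 + p2 - 1`, where `p1, p2` are the two trials' target
proportions, which makes it *exactly* invariant to which image of the
pair is designated — a property the test suite checks to 1e-12. Any
stable preference for one image (or side) cancels, which is the score's
purpose; the cancellation is verified on simulations that contain
baseline preferences and no knowledge effect.

A word-pair score for a subject is the mean over its image-pairs, but an
image-pair contributes only when **both** of its presentations survive
exclusion. When only one image-pair is complete its score is used alone
(n = 1 is recorded); when neither is, the word-pair score is missing —
a value, not an error. Item means average defined scores over subjects;
subject means average over a subject's defined word-pairs; grand means
are unweighted means of those marginals.

## Inference on scores

* **Bootstrap**: percentile intervals from 10,000 resamples. Subjects
  are the exchangeable unit, so subject-level and grand means resample
  subjects; an item's CI resamples the subjects contributing to that
  item. Seeds are recorded in every result.
* **Wilcoxon signed-rank** against zero, two-sided, zeros dropped.
  Without ties the p-value is the exact signed-rank distribution up to
  n = 25; with tied magnitudes an exact sign-flip enumeration is used up
  to n = 16, beyond which the normal approximation with continuity and
  tie corrections applies.
* **Exact sign (binomial) test** of the count of positive scores against
  a fair coin, two-sided by summing the probabilities of all outcomes no
  more likely than the observed one.
* **Cohen's d** as mean over sample SD (n − 1).
* **Kendall tau-b** between subject means and age in months, exact p for
  small untied samples.
* A **random-intercept LMM**, `score ~ 1 + (1 | subject)` by REML, asks
  whether the mean score is positive while letting subjects vary.
  The intercept's t-test uses Satterthwaite degrees of freedom; its
  likelihood-ratio test refits full and zero-intercept null models by
  ML. The Wald interval is the default (the profile interval is
  available) because it is fast, stable at these sample sizes, and the
  two agree to well within reporting precision here.

All tests are two-sided throughout: that convention is conservative and
is the one under which the reference p-values this package's exact
tests reproduce (0.50 for 2-of-2, 0.118 for 11-of-15) obtain.

## The pre/post-naming binomial mixed logit

The complementary analysis uses all non-excluded trials, not just
complete image-pairs. Each trial contributes two binomial observations:
the number of 20 ms bins on the target vs. on the distractor in the
pre-naming window, and the same in the analysis window. Away bins are
neither success nor failure and are dropped. A bin's state is the role
occupying the majority of it; ties break toward the role active at the
instant the bin starts; the trailing partial bin of a window is dropped
(156 analysis bins, 18 pre-naming bins at 20 ms). The binomial-count
formulation is the natural dichotomous response for a logit model of
"the ratio of looking times in number of 20 ms bins".

The model is `cbind(target, distractor) ~ phase + (1 | subject) +
(1 | item)` with `PRE` as the reference level, fitted by Laplace
approximation (`lme4::glmer`). The honorifics design uses subject-only
intercepts (2 items cannot support an item variance). The exponentiated
phase coefficient is the **phase odds ratio**: the multiplicative change
in the odds that a gaze bin is on-target after naming. The extended
model adds standardised age and its interaction with phase — age is
z-scored by default so the age odds ratio has a per-SD interpretation;
raw months are available by option. Models are compared by
likelihood-ratio test (the Laplace criterion is the ML objective here).
Separation (a level with all-target or all-distractor bins) triggers a
warning and a Haldane-style 0.5 pseudo-count refit.

Cohen's d for logit effects is reported via the standard conversion
`d = log(OR) * sqrt(3) / pi`. A d computed this way from an OR near 1.3
is small (~0.14); reported d values attached to such ORs in this
literature are often much larger and must come from a different,
unstated standardiser, so no claim is made to reproduce them — both the
mean/SD d (for scores) and the logit conversion (for ORs) are provided.

## The timecourse

At every 33 ms interval (two video frames) from −1000 to 3500 ms, each
usable trial contributes its bin state; the curve is the proportion of
on-target contributions out of contributions to either image. Pooling is
at the trial level (an infant with four usable trials contributes four
states per interval), the common convention; subject-first averaging is
available by option. Interval CIs are percentile bootstraps over
subjects. The overlay is a local quadratic regression weighted by the
number of either-image contributions per interval, span 0.25 — the span
and the plot range are presentation choices, documented rather than
claimed as canonical. The post-onset curve, weighted by its
contribution counts, time-averages to the pooled analysis-window target
proportion (a conservation check in the test suite).

## The synthetic gaze process

The simulator generates data with the statistical structure the
analyses assume, so that every stage can be validated by parameter
recovery without any field data. Gaze is a first-order Markov chain
over 20 ms bins: with probability `stay_prob` the current state
persists; otherwise a fresh state is drawn — `AWAY` with probability
`away_prob`, else `TARGET` with probability `plogis(eta)`. Because the
redraw distribution is state-independent, the chain's stationary
distribution *is* the redraw distribution, so `eta` is exactly the
stationary log-odds of target vs. distractor looking.

Before 367 ms, `eta` is the baseline image-preference contrast (per-image
offsets, SD `baseline_image_pref_sd`); from 367 ms on it adds the
knowledge effect `beta`, subject and item random effects, and
`age_slope` times standardised age. Switching at the analysis-window
boundary rather than at word onset aligns the latent truth with the
analysis contrast. Runs of target/distractor states become look
records; away runs become uncoded gaps; crying and adult-error flags
are drawn per trial.

Defaults are the study conditions this package is built around:
21 subjects aged 5.33–15.43 months; 8 noun-pairs × 2 image-pairs × 2
targets (32 trials) or 2 honorific-pairs (8 trials); `beta = 0.25`
(odds ratio ≈ 1.28, the size of effect these designs are powered for);
`age_slope = 0.077` (odds ratio ≈ 1.08 per SD of age). Where the
design's conditions do not pin a parameter down, values were chosen
once for realism and not revisited: subject and item effect SDs of 0.3
and 0.2 logits (moderate heterogeneity, comparable to the fixed
effect); image-preference SD 0.3; `away_prob = 0.15` (infants look away
roughly a sixth of the time); `stay_prob = 0.9`, i.e. geometric gaze
runs with mean 200 ms, at the short end of infant fixation durations so
that window-averaged looking tracks the latent preference; crying and
error rates of 2% and 1% of trials.

**What the simulator does and does not emulate.** It reproduces the
design, the window structure, autocorrelated gaze with away time,
baseline preferences that the difference score must cancel, random
effects at both levels, age dependence, and trial contamination. It
does not model saccade latencies, incremental word recognition within
the trial, drift in attention over the session, or coder error. Passing
recovery tests therefore show that the *pipeline* measures what it
claims on data with this structure — not that real infant gaze has this
structure.

Two consequences of the Markov persistence matter for interpretation.
First, state at the 367 ms switch carries over, so the window-averaged
effect is slightly smaller than `beta` (the carryover alone costs about
6% at the default persistence, and the unmodelled post-naming
heterogeneity attenuates the fixed effect a little further) — recovery
of the phase coefficient is therefore expected to show a small negative
bias, and the recovery tolerance (|bias| < 0.03 logits) accounts for
it. Because the true bias sits near that band, the recovery study uses
enough replicates (800) to keep its own Monte-Carlo standard error an
order of magnitude below the band; per-replicate estimates scatter with
SD ≈ 0.11 logits, which is the overdispersion cost of persistence. Second, persistence and the
post-naming-only heterogeneity overdisperse the binomial counts, so
model-based Wald intervals undercover *under the full generator*; the
nominal-coverage check is run under a well-specified null
(`stay_prob = 0`, no unmodelled heterogeneity), where the binomial
logit model is exactly the generating process.

## Numerical choices and degenerate inputs

* Window boundaries half-open everywhere; the one-third threshold kept
  as `3133/3` exactly; strict inequality for exclusion.
* Bin labelling: majority occupancy; ties to the role at bin start; if
  no maximal role is active at the start, the maximal role that becomes
  active first within the bin; trailing partial bins dropped. Bins count
  from the window start (367 ms), not from a grid aligned to word onset.
* Proportions are undefined (an error naming the trial) when a trial has
  no looking to either image — such trials should have been excluded
  upstream, so this error is a pipeline-integrity signal.
* Degenerate fits: a single-subject mixed logit collapses to ordinary
  logistic regression (checked against `glm`); zero-variance balanced
  LMMs return the grand mean exactly; an all-identical bootstrap input
  warns and returns a degenerate interval.
* The study-level fast paths (vectorised window summaries and bin
  counts) are checked for exact agreement with the per-trial reference
  implementations on simulated fixtures, and those against an
  independent 1 ms brute-force oracle.

## Problem sizes used in validation

The test suite validates effect recovery on 800 replicates of the full
21-subject nouns design (and 200 well-specified null replicates for
coverage); score-level null behaviour on 30 replicates; the bootstrap on
200 simulated cohorts of 8 units. These sizes give Monte-Carlo standard
errors comfortably below the tolerances being asserted (for example,
SE ≈ 0.004 logits for the recovery bias against a 0.03 band). The
analysis workflow under `analysis/` runs single cohorts and a 50-replicate
recovery study.

## Known limitations

* Reaction-time and first-shift analyses, onset-contingent splits, and
  cluster-based permutation tests over time are out of scope.
* The LMM reports random intercepts only, as the score model has one
  observation per subject × item.
* With tied magnitudes and 17 ≤ n ≤ 25 the Wilcoxon p falls back to the
  corrected normal approximation rather than full enumeration.
* The mixed logit treats bins within a trial-phase as conditionally
  independent; on strongly autocorrelated gaze its Wald statistics are
  anti-conservative. The package reports them as the field convention
  does, and quantifies the consequence in the recovery study.
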