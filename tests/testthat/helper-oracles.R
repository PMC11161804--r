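# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and the stats:: routines the package delegates to),
# re-deriving each quantity from first principles on small inputs.

# Exact two-sided sign-test p: enumerate the full binomial pmf and sum the
# probabilities of all outcomes no more likely than the observed one.
oracle_sign_p <- function(k, n) {
  pmf <- choose(n, 0:n) * 0.5^n
  sum(pmf[pmf <= pmf[k + 1] + 1e-12])
}

# Exact two-sided signed-rank p: enumerate all 2^n sign assignments of the
# ranked absolute deviations and count rank sums at least as extreme
# (distance from the permutation mean) as observed.
oracle_wilcoxon_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  v_obs <- sum(r[x > 0])
  mu <- sum(r) / 2
  total <- 0L
  hits <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    v <- sum(r[signs])
    total <- total + 1L
    if (abs(v - mu) >= abs(v_obs - mu) - 1e-9) hits <- hits + 1L
  }
  hits / total
}

# Millisecond-resolution window summary: paint each coded look onto a 1 ms
# grid and count. Independent interval arithmetic for conservation and
# classification checks.
oracle_window_summary <- function(looks, start_ms, end_ms) {
  n <- end_ms - start_ms
  grid <- rep("AWAY", n)
  for (i in seq_len(nrow(looks))) {
    a <- max(looks$onset_ms[i], start_ms)
    b <- min(looks$offset_ms[i], end_ms)
    if (b > a) {
      grid[(a - start_ms + 1):(b - start_ms)] <- looks$role[i]
    }
  }
  c(target_ms = sum(grid == "TARGET"),
    distractor_ms = sum(grid == "DISTRACTOR"),
    away_ms = sum(grid == "AWAY"))
}

# Trial exclusion re-derived from the millisecond grid.
oracle_classify <- function(looks, crying, error) {
  pre <- oracle_window_summary(looks, 0, 367)
  ana <- oracle_window_summary(looks, 367, 3500)
  reasons <- c(
    NO_PRENAMING_LOOK = unname(pre["target_ms"] + pre["distractor_ms"]) == 0,
    CRYING = crying,
    MIN_LOOKING =
      unname(ana["target_ms"] + ana["distractor_ms"]) < 3133 / 3,
    ADULT_ERROR = error
  )
  reasons
}

# Group-by aggregation of scores with base R only.
oracle_item_means <- function(scores) {
  d <- scores[!is.na(scores$score), ]
  v <- c(tapply(d$score, d$word_pair_id, mean))
  v[order(names(v))]
}
oracle_subject_means <- function(scores) {
  d <- scores[!is.na(scores$score), ]
  v <- c(tapply(d$score, d$subject_id, mean))
  v[order(names(v))]
}
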