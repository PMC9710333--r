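# Independent oracles used across the suite.

# Bisection inversion oracle: find scr in [lo, hi] with fwd(scr) == target,
# independent of the package's closed-form / uniroot inversions.
bisect_invert <- function(fwd, target, lo = 0.05, hi = 25, iter = 80) {
  flo <- fwd(lo) - target
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    fm <- fwd(mid) - target
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else hi <- mid
  }
  (lo + hi) / 2
}

# Two-sided Fisher exact p by hypergeometric enumeration for the table
# [[a, b], [c, d]]: sum of probabilities of all tables (same margins) no
# more probable than the observed one (relative tolerance as in R).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  pr <- dhyper(support, m, n, k)
  sum(pr[pr <= pr[support == a] * (1 + 1e-7)])
}

# a small deterministic hand-built cohort for I/O and classification tests
tiny_cohort <- function() {
  data.frame(
    id = c("A1", "A2", "A3", "A4"),
    age = c(40, 38, 70, 25),
    sex = c("male", "female", "female", "male"),
    hiv = c(1L, 0L, 1L, NA),
    art = c(1L, 0L, 0L, NA),
    weight = c(72, 60, 55, 68),
    height = c(172, 160, 155, 175),
    sbp = c(90, 120, 100, 130),
    dbp = c(60, 80, 70, 85),
    rr = c(24, 18, 22, 16),
    gcs = c(15L, 15L, 14L, 15L),
    cr0 = c(2.7, 0.7, 1.4, 1.0),
    cr48 = c(2.3, 0.72, NA, 1.05),
    cr3m = c(1.1, 0.68, 1.6, NA),
    haematuria = c(1L, 0L, 0L, 0L),
    proteinuria = c(0L, 0L, 1L, 0L),
    ri = c(0.70, 0.58, 0.66, 0.60),
    died = c(0L, 0L, 0L, 1L),
    futime = c(92, 95, 88, 30),
    stringsAsFactors = FALSE)
}

# noise-free, fully-observed generator settings for exact-agreement checks
noisefree_config <- function(seed, n = 101, ...) {
  synth_config(n = n, seed = seed, noise_cv = 0, missing_cr48 = 0,
               missing_cr3m = 0, lost_to_followup = 0, ...)
}
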