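# Shared fixtures: the published agreement-study ANOVA tables and small
# deterministic grids, plus brute-force oracles used across test files.

# 24 children scored by 10 emergency-room staffers (full data)
agreement_study_summary <- function() {
  anova_summary(95.450, 4.414, 0.786, icc_design(24, 10))
}

# same study after deleting one child and transforming the scores
agreement_study_reduced_summary <- function() {
  anova_summary(8.3721, 0.3667, 0.0671, icc_design(23, 10))
}

# 2 x 2 grid with hand-computable sums of squares
tiny_grid <- function() {
  icc_data(matrix(c(1, 3, 2, 5), nrow = 2, ncol = 2))
}

random_grid <- function(b0, l0, r0 = 1, seed = 1) {
  set.seed(seed)
  icc_data(array(rnorm(b0 * l0 * r0), dim = c(b0, l0, r0)))
}

# exhaustive shortest-window HPD: checks every contiguous window of
# ceiling(level * n) sorted draws
hpd_brute_force <- function(x, level) {
  s <- sort(x)
  n <- length(s)
  k <- ceiling(level * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - k + 1)) {
    if (s[i + k - 1] - s[i] < best[2] - best[1])
      best <- c(s[i], s[i + k - 1])
  }
  best
}

sample_skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3

sample_kurtosis <- function(x) mean((x - mean(x))^4) / stats::var(x)^2
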