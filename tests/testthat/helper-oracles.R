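# Independent oracles used to cross-check package estimators. Each is a
# direct transcription of the defining formula, kept free of any package
# code path it validates.

# OLS slope by the textbook covariance formula
ols_slope_oracle <- function(t, y) {
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

# Pearson r by the textbook formula
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Benjamini-Hochberg step-up from the definition: sort ascending,
# q_(i) = min_{j >= i} n p_(j) / j, restore input order
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(1, min(n * ps[i:n] / (i:n)))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# Welch t statistic and two-sided p from the textbook formulas
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# Monte-Carlo power of the two-sided two-sample t-test (vectorized)
power_mc_oracle <- function(n, d, alpha, reps = 1e5, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(reps * n), reps)
  y <- matrix(rnorm(reps * n, mean = d), reps)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (n - 1)
  vy <- rowSums((y - my)^2) / (n - 1)
  sp2 <- (vx + vy) / 2
  t <- (my - mx) / sqrt(sp2 * 2 / n)
  mean(abs(t) > qt(1 - alpha / 2, 2 * n - 2))
}

# small fast generator configs for tests
fast_config <- function(...) {
  generatorConfig(
    benign = groupConfig(n_samples = 3, noise_sd = 0.1, bio_cv = 0.1),
    tumor = groupConfig(n_samples = 3, noise_sd = 0.1, bio_cv = 0.1,
                        true_jo2 = c(E = 7, PM = 10.5, PMD = 21, PMDG = 28,
                                     PMDGS = 35, M = 8.4, MPC = 14,
                                     MPCD = 21),
                        coupling_fraction = 0.80, content_scale = 0.5,
                        amount = 3.5, protein_ug_per_mg = 100),
    n_features = 600, n_samples_proteome = 4, n_samples_transcriptome = 4,
    ...)
}

noiseless_config <- function(...) {
  generatorConfig(
    benign = groupConfig(n_samples = 2, noise_sd = 0, bio_cv = 0,
                         detection_dropout_rate = 0),
    tumor = groupConfig(n_samples = 2, noise_sd = 0, bio_cv = 0,
                        detection_dropout_rate = 0,
                        true_jo2 = c(E = 7, PM = 10.5, PMD = 21, PMDG = 28,
                                     PMDGS = 35, M = 8.4, MPC = 14,
                                     MPCD = 21),
                        coupling_fraction = 0.80, content_scale = 0.5,
                        amount = 3.5, protein_ug_per_mg = 100),
    n_features = 600, abundance_log2_sd = 0,
    n_samples_proteome = 3, n_samples_transcriptome = 3, ...)
}
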