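## Two-sample statistics used throughout the pipeline. Thin wrappers over
## base R where base R provides the estimator; the noncentral-t power
## construction is implemented here directly.

#' Two-sample t-test (Welch default, pooled-variance option)
#'
#' @param a,b numeric vectors (each >= 2 values).
#' @param pooled use the pooled-variance Student variant instead of Welch.
#' @return list with `t` and `p` (two-tailed).
#' @examples
#' welchT(c(0, 1, 2), c(3, 4, 5), pooled = TRUE)
#' @export
welchT <- function(a, b, pooled = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    stop("zero variance in both groups with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = pooled)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Cohen's d
#'
#' Standardized mean difference `(mean(a) - mean(b)) / s_pooled`, with the
#' pooled SD using n-1 weights.
#'
#' @param a,b numeric vectors.
#' @return numeric effect size.
#' @examples
#' cohensD(c(0, 1, 2), c(3, 4, 5))  # -3
#' @export
cohensD <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) stop("pooled SD is zero")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Coefficient of variation (percent)
#'
#' @param x numeric vector with non-zero mean.
#' @return `100 * sd(x) / mean(x)`.
#' @export
cvPercent <- function(x) {
  if (mean(x) == 0) stop("CV undefined for zero mean")
  100 * stats::sd(x) / mean(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotone enforcement; ties preserved and
#' input order restored (delegates to [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Power of the two-sided two-sample t-test
#'
#' Computed from the noncentral t distribution: with `n` per group,
#' standardized effect `d`, and two-sided level `alpha`, the test statistic
#' under the alternative is noncentral t with `df = 2n - 2` and
#' noncentrality `ncp = d * sqrt(n / 2)`; power is the probability mass of
#' that distribution beyond the two-sided critical values. At `d = 0` this
#' reduces to `alpha`. Unequal group sizes are handled by the
#' harmonic-mean effective n.
#'
#' @param n_per_group samples per group (>= 2); a length-2 vector gives
#'   unequal sizes via the harmonic mean.
#' @param d Cohen's d.
#' @param alpha two-sided significance level in (0, 1).
#' @return power in `[0, 1]`.
#' @examples
#' powerTwoSampleT(14, 2.88, 0.05)  # > 0.99
#' @export
powerTwoSampleT <- function(n_per_group, d, alpha = 0.05) {
  stopifnot(all(n_per_group >= 2), alpha > 0, alpha < 1, is.finite(d))
  if (length(n_per_group) == 2) {
    df <- sum(n_per_group) - 2
    n_eff <- 2 / (1 / n_per_group[1] + 1 / n_per_group[2])
  } else {
    df <- 2 * n_per_group - 2
    n_eff <- n_per_group
  }
  ncp <- d * sqrt(n_eff / 2)
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tcrit, df, ncp = ncp) + 1 - stats::pt(tcrit, df, ncp = ncp)
}

#' Pearson correlation
#'
#' @param x,y numeric vectors (>= 3 pairs, non-constant).
#' @return sample Pearson r.
#' @export
pearsonR <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Pearson r undefined for constant input")
  stats::cor(x, y)
}
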