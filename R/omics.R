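## Detection sets, differential abundance, mitochondrial summaries, and
## transcriptome-proteome integration.

#' Partition features by detection group
#'
#' A feature counts as detected in a group when it is observed in at least
#' `minSamples` of that group's samples. Features detected in both groups
#' are `shared`; the rest are group-exclusive. The three sets are pairwise
#' disjoint and their union is every detected feature.
#'
#' @param abundance an [AbundanceExperiment-class] (uses its `detected`
#'   assay).
#' @param minSamples detection threshold per group (default 3, robust to
#'   single-sample artifacts).
#' @return list with character vectors `shared`, `group1_only`,
#'   `group2_only`, plus `groups` naming which group is which.
#' @export
detectFeatures <- function(abundance, minSamples = 3) {
  stopifnot(minSamples >= 1)
  det <- assay(abundance, "detected")
  grp <- sampleGroups(abundance)
  gl <- unique(grp)
  if (length(gl) != 2L) stop("exactly two groups are required")
  sizes <- table(grp)
  if (minSamples > min(sizes))
    stop("minSamples exceeds the smallest group size (", min(sizes), ")")
  in_g <- vapply(gl, function(g)
    rowSums(det[, grp == g, drop = FALSE]) >= minSamples,
    logical(nrow(det)))
  feats <- rownames(det)
  list(shared = feats[in_g[, 1] & in_g[, 2]],
       group1_only = feats[in_g[, 1] & !in_g[, 2]],
       group2_only = feats[!in_g[, 1] & in_g[, 2]],
       groups = gl)
}

## Row-wise Welch t on log2 values; vectorized for matrices. Equality with
## stats::t.test is asserted in the unit tests.
.rowWelch <- function(x, grp) {
  gl <- unique(grp)
  stats_for <- function(g) {
    m <- x[, grp == g, drop = FALSE]
    n <- rowSums(!is.na(m))
    mu <- rowMeans(m, na.rm = TRUE)
    v <- rowSums((m - mu)^2, na.rm = TRUE) / pmax(n - 1, 1)
    list(n = n, mu = mu, v = v)
  }
  s1 <- stats_for(gl[1]); s2 <- stats_for(gl[2])
  se2 <- s1$v / s1$n + s2$v / s2$n
  t <- (s2$mu - s1$mu) / sqrt(se2)
  df <- se2^2 / ((s1$v / s1$n)^2 / (s1$n - 1) + (s2$v / s2$n)^2 / (s2$n - 1))
  p <- 2 * stats::pt(-abs(t), df)
  zerovar <- s1$v == 0 & s2$v == 0
  flat <- zerovar & (s2$mu == s1$mu)
  p[zerovar] <- 1  # no within-group variance: flagged, never NaN
  t[flat] <- 0
  list(t = t, p = p, n1 = s1$n, n2 = s2$n, diff = s2$mu - s1$mu,
       zero_variance = zerovar)
}

#' Differential abundance between two groups
#'
#' For the shared (detected-in-both) features, computes per feature the
#' tumor-vs-benign log2 fold change as the difference of group means of
#' `log2(value + pseudocount)`, a Welch t-test p-value, and
#' Benjamini-Hochberg adjusted p-values; calls with `padj < 0.1` are
#' flagged significant. This is a deliberately simple stand-in used for
#' synthetic cohorts; externally produced DE tables are accepted as inputs
#' by [integrateLayers()] on equal footing.
#'
#' @param abundance an [AbundanceExperiment-class].
#' @param pseudocount added before log2; default 1 for protein intensities,
#'   0.5 for TPM.
#' @param minSamples detection threshold defining the shared set.
#' @return data.frame: `feature_id`, `gene_symbol`, `log2fc`, `p`, `padj`,
#'   `significant`, `direction` (`up`/`down`/`ns`), `zero_variance`.
#' @export
differentialAbundance <- function(abundance,
                                  pseudocount = if (abundanceLayer(abundance)
                                                    == "tpm") 0.5 else 1,
                                  minSamples = 3) {
  grp <- sampleGroups(abundance)
  if (min(table(grp)) < 2) stop("at least 2 samples per group are required")
  shared <- detectFeatures(abundance, minSamples)$shared
  if (!length(shared)) stop("no shared features")
  a <- assay(abundance, "abundance")[shared, , drop = FALSE]
  # order groups so the contrast is tumor (or second level) vs benign
  gl <- unique(grp)
  if (all(c("benign", "tumor") %in% gl)) gl <- c("benign", "tumor")
  x <- log2(a + pseudocount)
  w <- .rowWelch(x, factor(grp, levels = gl))
  padj <- stats::p.adjust(w$p, method = "BH")
  sig <- padj < 0.1
  data.frame(
    feature_id = shared,
    gene_symbol = rowData(abundance)[shared, "gene_symbol"],
    log2fc = w$diff, p = w$p, padj = padj, significant = sig,
    direction = ifelse(!sig, "ns", ifelse(w$diff > 0, "up", "down")),
    zero_variance = w$zero_variance, row.names = NULL)
}

#' Summed mitochondrial protein abundance
#'
#' Per-sample sum of all detected mitochondrial features (the numerator of
#' the MEF), with group means and SDs.
#'
#' @param abundance an [AbundanceExperiment-class], protein layer.
#' @return list with `per_sample` (named numeric) and `per_group`
#'   (data.frame `group`, `mean`, `sd`).
#' @export
summedMitoAbundance <- function(abundance) {
  a <- assay(abundance, "abundance")
  mito <- rowData(abundance)$is_mito
  per_sample <- colSums(a[mito, , drop = FALSE], na.rm = TRUE)
  grp <- sampleGroups(abundance)
  per_group <- do.call(rbind, lapply(split(per_sample, grp), function(x)
    data.frame(mean = mean(x), sd = stats::sd(x))))
  per_group <- data.frame(group = rownames(per_group), per_group,
                          row.names = NULL)
  list(per_sample = per_sample, per_group = per_group)
}

#' Per-complex OXPHOS subunit summaries
#'
#' For each respiratory complex CI..CV, the summed abundance of its
#' detected subunits divided by the summed abundance of the denominator
#' set: all mitochondrial features (`"mito"`) or the whole matrix
#' (`"total"`). The two denominators differ exactly by the sample's MEF.
#'
#' @param abundance an [AbundanceExperiment-class].
#' @param denominator `"mito"` or `"total"`.
#' @return matrix (5 complexes x samples) of relative abundances.
#' @export
complexSummaries <- function(abundance, denominator = c("mito", "total")) {
  denominator <- match.arg(denominator)
  a <- assay(abundance, "abundance")
  cx <- rowData(abundance)$complex
  den <- if (denominator == "mito") {
    sel <- rowData(abundance)$is_mito
    if (!any(sel)) stop("empty denominator: no mitochondrial features")
    colSums(a[sel, , drop = FALSE], na.rm = TRUE)
  } else colSums(a, na.rm = TRUE)
  if (any(den == 0)) stop("empty denominator for some sample(s)")
  out <- vapply(c("CI", "CII", "CIII", "CIV", "CV"), function(k)
    colSums(a[cx == k, , drop = FALSE], na.rm = TRUE) / den,
    numeric(ncol(a)))
  t(out)
}

#' Integrate transcriptome and proteome fold changes
#'
#' Matches DE tables from the two layers by gene symbol
#' (case-insensitive), correlates the log2 fold changes (Pearson), and
#' collects the jointly significant co-directional overlap sets. Duplicate
#' symbols within a layer are collapsed to one row: by maximum
#' `mean_abundance` when that column is present, otherwise by minimum
#' `padj` (ties broken by larger `|log2fc|`); collapsed symbols are listed
#' in the `collapsed` element.
#'
#' @param deRna,deProtein data.frames with at least `gene_symbol`,
#'   `log2fc`, `padj` (`significant` recomputed as `padj < 0.1` if absent).
#' @param annotation optional feature annotation supplying `is_mito` per
#'   gene symbol.
#' @return list: `pairs` (data.frame `gene_symbol, rna_log2fc,
#'   protein_log2fc, is_mito`), `r` (Pearson correlation), `down_down` and
#'   `up_up` (character vectors of jointly significant co-directional
#'   genes), `collapsed`.
#' @export
integrateLayers <- function(deRna, deProtein, annotation = NULL) {
  prep <- function(d) {
    d$key <- tolower(d$gene_symbol)
    if (is.null(d$significant)) d$significant <- d$padj < 0.1
    dup <- unique(d$key[duplicated(d$key)])
    if (length(dup)) {
      score <- if (!is.null(d$mean_abundance)) d$mean_abundance
               else -d$padj + 1e-12 * abs(d$log2fc)
      keep <- unlist(lapply(split(seq_len(nrow(d)), d$key), function(i)
        i[which.max(score[i])]))
      d <- d[sort(keep), , drop = FALSE]
    }
    attr(d, "collapsed") <- dup
    d
  }
  r1 <- prep(deRna); r2 <- prep(deProtein)
  common <- intersect(r1$key, r2$key)
  if (!length(common)) stop("no overlapping gene symbols between layers")
  i1 <- match(common, r1$key); i2 <- match(common, r2$key)
  is_mito <- if (!is.null(annotation))
    annotation$is_mito[match(common, tolower(annotation$gene_symbol))]
  else rep(NA, length(common))
  pairs <- data.frame(gene_symbol = r1$gene_symbol[i1],
                      rna_log2fc = r1$log2fc[i1],
                      protein_log2fc = r2$log2fc[i2],
                      is_mito = is_mito, row.names = NULL)
  joint <- r1$significant[i1] & r2$significant[i2]
  dn <- joint & r1$log2fc[i1] < 0 & r2$log2fc[i2] < 0
  up <- joint & r1$log2fc[i1] > 0 & r2$log2fc[i2] > 0
  list(pairs = pairs,
       r = pearsonR(pairs$rna_log2fc, pairs$protein_log2fc),
       down_down = pairs$gene_symbol[dn],
       up_up = pairs$gene_symbol[up],
       collapsed = union(attr(r1, "collapsed"), attr(r2, "collapsed")))
}
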