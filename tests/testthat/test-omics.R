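mini_experiment <- function(values, group, mito = NULL, complex = NULL,
                            layer = "protein") {
  n <- nrow(values)
  ann <- data.frame(feature_id = rownames(values),
                    gene_symbol = rownames(values),
                    is_mito = if (is.null(mito)) rep(TRUE, n) else mito,
                    complex = if (is.null(complex)) rep("none", n) else complex,
                    stringsAsFactors = FALSE)
  AbundanceExperiment(values, ann, group = group, layer = layer)
}

test_that("detection sets partition features by group occupancy", {
  det <- matrix(TRUE, 4, 6,
                dimnames = list(paste0("f", 1:4), paste0("s", 1:6)))
  det[2, 4:6] <- FALSE           # f2 only in group 1
  det[3, 1:3] <- FALSE           # f3 only in group 2
  det[4, c(1, 2, 4)] <- FALSE    # f4: 1/3 in g1, 2/3 in g2 -> nowhere at k=2
  v <- matrix(10, 4, 6, dimnames = dimnames(det))
  v[!det] <- NA
  ex <- mini_experiment(v, rep(c("benign", "tumor"), each = 3))
  ds <- detectFeatures(ex, minSamples = 2)
  expect_setequal(ds$shared, "f1")
  expect_setequal(ds$group1_only, "f2")
  expect_setequal(ds$group2_only, c("f3", "f4"))
  # pairwise disjoint partition
  expect_length(intersect(ds$shared, c(ds$group1_only, ds$group2_only)), 0)
  expect_error(detectFeatures(ex, minSamples = 4), "exceeds")
})

test_that("detection sets equal brute-force enumeration of a dropout mask", {
  cfg <- fast_config()
  cfg$benign$detection_dropout_rate <- 0.3
  cfg$tumor$detection_dropout_rate <- 0.3
  prot <- simulateProteome(cfg, seed = 17)
  det <- SummarizedExperiment::assay(prot, "detected")
  grp <- sampleGroups(prot)
  k <- 2
  ds <- detectFeatures(prot, minSamples = k)
  # independent per-cell enumeration over the mask
  brute <- t(apply(det, 1, function(row)
    c(sum(row[grp == "benign"]) >= k, sum(row[grp == "tumor"]) >= k)))
  feats <- rownames(det)
  expect_setequal(ds$shared, feats[brute[, 1] & brute[, 2]])
  expect_setequal(ds$group1_only, feats[brute[, 1] & !brute[, 2]])
  expect_setequal(ds$group2_only, feats[!brute[, 1] & brute[, 2]])
  expect_setequal(c(ds$shared, ds$group1_only, ds$group2_only),
                  feats[brute[, 1] | brute[, 2]])
})

test_that("differential abundance recovers exact effects and flags ties", {
  # identical groups: log2fc 0 everywhere
  v <- matrix(rep(c(8, 16, 32), 6), nrow = 3,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:6)))
  de0 <- differentialAbundance(
    mini_experiment(v, rep(c("benign", "tumor"), each = 3)),
    pseudocount = 0, minSamples = 2)
  expect_equal(de0$log2fc, rep(0, 3))
  expect_true(all(de0$p == 1 & de0$zero_variance))
  # noiseless 2-fold shift: log2fc exactly 1 (pseudocount 0)
  v2 <- v; v2[, 4:6] <- v[, 4:6] * 2
  de2 <- differentialAbundance(
    mini_experiment(v2, rep(c("benign", "tumor"), each = 3)),
    pseudocount = 0, minSamples = 2)
  expect_equal(de2$log2fc, rep(1, 3))
  # per-feature Welch p agrees with stats::t.test on noisy data
  set.seed(21)
  v3 <- matrix(2^rnorm(60, 8), 6,
               dimnames = list(paste0("f", 1:6), paste0("s", 1:10)))
  grp <- rep(c("benign", "tumor"), each = 5)
  de3 <- differentialAbundance(mini_experiment(v3, grp), pseudocount = 1,
                               minSamples = 2)
  for (i in 1:6) {
    ref <- t.test(log2(v3[i, grp == "tumor"] + 1),
                  log2(v3[i, grp == "benign"] + 1))
    expect_equal(de3$p[i], ref$p.value, tolerance = 1e-12)
  }
  expect_equal(de3$padj, p.adjust(de3$p, "BH"))
  expect_identical(de3$significant, de3$padj < 0.1)
})

test_that("estimated effect signs track the configured ground truth", {
  cfg <- generatorConfig(n_features = 1000, n_samples_proteome = 6)
  cfg$benign$detection_dropout_rate <- 0
  cfg$tumor$detection_dropout_rate <- 0
  prot <- simulateProteome(cfg, seed = 31)  # tumor mito content 0.5 => fc<0
  de <- differentialAbundance(prot, minSamples = 3)
  mito <- SummarizedExperiment::rowData(prot)[de$feature_id, "is_mito"]
  expect_gte(mean(de$log2fc[mito] < 0), 0.95)
})

test_that("summed mito abundance matches hand totals and the MEF numerator", {
  v <- matrix(c(30, 50, 20, 10, 5, 1), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  ex <- mini_experiment(v, c("benign", "tumor"),
                        mito = c(TRUE, TRUE, FALSE))
  sm <- summedMitoAbundance(ex)
  expect_equal(unname(sm$per_sample), c(80, 15))
  # zero when nothing is mitochondrial
  none <- summedMitoAbundance(mini_experiment(v, c("benign", "tumor"),
                                              mito = rep(FALSE, 3)))
  expect_equal(unname(none$per_sample), c(0, 0))
  # internal consistency: equals MEF numerator exactly
  prot <- simulateProteome(fast_config(), seed = 12)
  mef <- computeMEF(prot)
  a <- SummarizedExperiment::assay(prot, "abundance")
  tot <- colSums(a, na.rm = TRUE)
  expect_equal(summedMitoAbundance(prot)$per_sample, mef$per_sample * tot)
})

test_that("complex summaries divide by the chosen denominator", {
  v <- matrix(c(10, 20, 30, 40, 50, 150,
                1, 2, 3, 4, 5, 15), nrow = 6,
              dimnames = list(paste0("f", 1:6), c("s1", "s2")))
  cx <- c("CI", "CII", "CIII", "CIV", "CV", "none")
  ex <- mini_experiment(v, c("benign", "tumor"),
                        mito = c(rep(TRUE, 5), FALSE), complex = cx)
  cs_mito <- complexSummaries(ex, "mito")
  # hand-computed: mito total 150 in s1; CI 10/150 etc.
  expect_equal(cs_mito[, "s1"],
               c(CI = 10, CII = 20, CIII = 30, CIV = 40, CV = 50) / 150)
  cs_tot <- complexSummaries(ex, "total")
  expect_equal(cs_tot[, "s1"],
               c(CI = 10, CII = 20, CIII = 30, CIV = 40, CV = 50) / 300)
  # the two denominators differ exactly by the sample MEF
  mef <- computeMEF(ex)$per_sample
  expect_equal(cs_tot, sweep(cs_mito, 2, mef, "*"))
  # a single complex holding all mito abundance -> ratio 1
  one <- mini_experiment(v[1:2, , drop = FALSE], c("benign", "tumor"),
                         mito = c(TRUE, FALSE), complex = c("CI", "none"))
  expect_equal(complexSummaries(one, "mito")["CI", ], c(s1 = 1, s2 = 1))
  expect_error(complexSummaries(
    mini_experiment(v, c("benign", "tumor"), mito = rep(FALSE, 6)), "mito"),
    "empty denominator")
})

test_that("layer integration correlates fold changes and finds overlaps", {
  de <- data.frame(gene_symbol = c("A", "B", "C", "D", "E"),
                   log2fc = c(-2, -1, 0.5, 1.5, -0.3),
                   padj = c(0.01, 0.05, 0.5, 0.02, 0.3))
  # protein copied from rna: r = 1
  self <- integrateLayers(de, de)
  expect_equal(self$r, 1)
  # hand-enumerated overlap: A and B jointly significant and down
  expect_setequal(self$down_down, c("A", "B"))
  expect_setequal(self$up_up, "D")
  # matching is case-insensitive
  de2 <- transform(de, gene_symbol = tolower(gene_symbol))
  expect_equal(nrow(integrateLayers(de, de2)$pairs), 5)
  # duplicates collapse to the row with the smallest padj
  dup <- rbind(de, data.frame(gene_symbol = "A", log2fc = 5, padj = 0.9))
  out <- integrateLayers(dup, de)
  expect_equal(out$pairs$rna_log2fc[out$pairs$gene_symbol == "A"], -2)
  expect_true("a" %in% out$collapsed)
  expect_error(integrateLayers(de, transform(de, gene_symbol = paste0("X",
    gene_symbol))), "no overlapping")
})

test_that("null fold changes show no spurious correlation vs permutation", {
  set.seed(33)
  n <- 200
  de_rna <- data.frame(gene_symbol = paste0("g", 1:n),
                       log2fc = rnorm(n), padj = runif(n))
  de_prot <- data.frame(gene_symbol = paste0("g", 1:n),
                        log2fc = rnorm(n), padj = runif(n))
  obs <- integrateLayers(de_rna, de_prot)$r
  perm <- replicate(200, pearson_oracle(de_rna$log2fc,
                                        sample(de_prot$log2fc)))
  # observed |r| within the permutation null band
  expect_lt(abs(obs), quantile(abs(perm), 0.999))
})
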