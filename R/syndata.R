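## Synthetic cohort generator. Every downstream stage of the pipeline is
## validated against cohorts drawn here, where the ground truth (flux
## ladders, coupling fractions, effect sizes, dropout masks, cell-type
## tables) is known exactly.

.protocolStates <- list(
  CI_CII = c("E", "PM", "PMD", "PMDG", "PMDGS"),
  CI_CII_coupling = c("E", "PM", "PMD", "PMDG", "PMDGS", "OMY", "AMA", "AMA_ROT"),
  LIPID = c("E", "M", "MPC", "MPCD")
)

.protocolEvents <- list(
  CI_CII = c("PM", "D", "G", "S"),
  CI_CII_coupling = c("PM", "D", "G", "S", "OMY", "AMA", "ROT"),
  LIPID = c("M", "PC", "D")
)

#' Per-group generator settings
#'
#' @param n_samples biological samples per group (each yields two technical
#'   replicate traces).
#' @param true_jo2 named numeric vector of true steady-state fluxes
#'   (pmol O2 s-1 mg-1 wet weight) for the substrate states
#'   `E, PM, PMD, PMDG, PMDGS` and the lipid-protocol states `M, MPC, MPCD`.
#' @param coupling_fraction fraction of maximal PMDGS respiration abolished
#'   by oligomycin (ATP-synthase-linked share), in `[0, 1]`.
#' @param residual_fraction fraction of PMDGS flux remaining after
#'   antimycin A + rotenone, in `[0, 1]`.
#' @param noise_sd additive Gaussian noise on the O2 trace, uM.
#' @param bio_cv between-sample coefficient of variation of the whole flux
#'   ladder (multiplicative log-normal sample factor; 0 disables).
#' @param content_scale positive factor multiplying all mitochondrial
#'   protein abundances of the group.
#' @param mito_log2fc additional log2 shift applied to this group's
#'   mitochondrial features in the proteome (and non-OXPHOS mitochondrial
#'   transcripts), on top of `content_scale`.
#' @param detection_dropout_rate per feature-x-sample Bernoulli probability
#'   that a protein measurement is missing.
#' @param amount tissue loaded per chamber, mg wet weight.
#' @param protein_ug_per_mg true group mean total protein content,
#'   ug protein per mg wet weight (Bradford-style).
#'
#' @return list of class `groupConfig`.
#' @export
groupConfig <- function(n_samples = 14,
                        true_jo2 = c(E = 1, PM = 1.5, PMD = 3, PMDG = 4,
                                     PMDGS = 5, M = 1.2, MPC = 2, MPCD = 3),
                        coupling_fraction = 0.55,
                        residual_fraction = 0.02,
                        noise_sd = 0.2,
                        bio_cv = 0.30,
                        content_scale = 1,
                        mito_log2fc = 0,
                        detection_dropout_rate = 0.1,
                        amount = 18,
                        protein_ug_per_mg = 80) {
  structure(list(
    n_samples = as.integer(n_samples), true_jo2 = true_jo2,
    coupling_fraction = coupling_fraction,
    residual_fraction = residual_fraction,
    noise_sd = noise_sd, bio_cv = bio_cv,
    content_scale = content_scale, mito_log2fc = mito_log2fc,
    detection_dropout_rate = detection_dropout_rate,
    amount = amount, protein_ug_per_mg = protein_ug_per_mg),
    class = "groupConfig")
}

#' Full generator configuration
#'
#' The defaults encode the study conditions the generator emulates: benign
#' mammary tissue versus HER2-driven tumor, a tumor/benign wet-weight PMDGS
#' ratio of 7 (tumors respire several-fold higher per mg), oligomycin
#' coupling fractions 0.55 (benign) and 0.80 (tumor), near-complete
#' inhibition by antimycin A + rotenone, and a tumor mitochondrial proteome
#' scaled to 50% of benign content.
#'
#' @param benign,tumor [groupConfig()] objects.
#' @param n_features total proteome/transcriptome features.
#' @param frac_mito fraction of features flagged mitochondrial (must leave
#'   room for the 84 built-in OXPHOS subunits).
#' @param abundance_log2_sd per-measurement log2-scale noise of simulated
#'   abundances.
#' @param complex_log2fc named log2 shifts of tumor OXPHOS transcript
#'   blocks per complex (`CI`..`CV`).
#' @param n_samples_proteome,n_samples_transcriptome samples per group for
#'   the omics layers.
#' @param chamber_volume_ml oxygraph chamber volume (ml).
#' @param start_o2 starting chamber O2 concentration (uM).
#' @param dt_s trace sampling interval (s).
#' @param state_duration_s duration of each titration state segment (s).
#' @param seed default RNG seed used when a simulator is called without one.
#'
#' @return list of class `GeneratorConfig`.
#' @examples
#' cfg <- generatorConfig()
#' cfg$tumor$coupling_fraction
#' @export
generatorConfig <- function(
    benign = groupConfig(),
    tumor = groupConfig(
      true_jo2 = c(E = 7, PM = 10.5, PMD = 21, PMDG = 28, PMDGS = 35,
                   M = 8.4, MPC = 14, MPCD = 21),
      coupling_fraction = 0.80,
      content_scale = 0.5,
      amount = 3.5,
      protein_ug_per_mg = 100),
    n_features = 2000,
    frac_mito = 0.15,
    abundance_log2_sd = 0.5,
    complex_log2fc = c(CI = -1, CII = -1, CIII = -1, CIV = -1, CV = 0),
    n_samples_proteome = 5,
    n_samples_transcriptome = 6,
    chamber_volume_ml = 2,
    start_o2 = 180,
    dt_s = 2,
    state_duration_s = 300,
    seed = 1L) {
  cfg <- structure(list(
    benign = benign, tumor = tumor,
    n_features = as.integer(n_features), frac_mito = frac_mito,
    abundance_log2_sd = abundance_log2_sd, complex_log2fc = complex_log2fc,
    n_samples_proteome = as.integer(n_samples_proteome),
    n_samples_transcriptome = as.integer(n_samples_transcriptome),
    chamber_volume_ml = chamber_volume_ml, start_o2 = start_o2,
    dt_s = dt_s, state_duration_s = state_duration_s,
    seed = as.integer(seed)), class = "GeneratorConfig")
  validateGeneratorConfig(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks the invariants the simulators rely on: fractions in `[0, 1]`, at
#' least two samples per group, non-negative fluxes, and a monotone
#' substrate ladder `E <= PM <= PMD <= PMDG <= PMDGS`.
#'
#' @param cfg a [generatorConfig()] object.
#' @return `cfg`, invisibly; stops on violation.
#' @export
validateGeneratorConfig <- function(cfg) {
  for (g in c("benign", "tumor")) {
    gc <- cfg[[g]]
    if (gc$n_samples < 2L)
      stop(g, ": n_samples must be >= 2")
    fr <- c(coupling_fraction = gc$coupling_fraction,
            residual_fraction = gc$residual_fraction,
            detection_dropout_rate = gc$detection_dropout_rate)
    bad <- names(fr)[fr < 0 | fr > 1]
    if (length(bad))
      stop(g, ": fraction(s) outside [0,1]: ", paste(bad, collapse = ", "))
    if (any(gc$true_jo2 < 0))
      stop(g, ": true_jo2 values must be >= 0")
    ladder <- gc$true_jo2[c("E", "PM", "PMD", "PMDG", "PMDGS")]
    if (any(diff(ladder) < 0))
      stop(g, ": substrate ladder must be non-decreasing E..PMDGS")
    if (gc$noise_sd < 0) stop(g, ": noise_sd must be >= 0")
    if (gc$bio_cv < 0) stop(g, ": bio_cv must be >= 0")
    if (gc$content_scale <= 0) stop(g, ": content_scale must be > 0")
    if (gc$amount <= 0) stop(g, ": amount must be > 0")
  }
  if (cfg$frac_mito < 0 || cfg$frac_mito > 1)
    stop("frac_mito must be in [0,1]")
  invisible(cfg)
}

#' Content-only contrast configuration
#'
#' Builds a two-group scenario in which the tumor group has its
#' mitochondrial content scaled by `content_scale` but an *identical
#' intrinsic flux per unit mitochondrial protein*. Wet-weight flux then
#' differs by the mitochondrial-protein-per-mg ratio, while MEF-normalized
#' flux is equal by construction. Because the mitochondrial enrichment
#' factor is a ratio, scaling mito abundance by `c` changes the group MEF
#' from `m` to `c m / (c m + 1 - m)`, and the wet-weight ladder is scaled
#' accordingly (total protein per mg is held equal across groups).
#'
#' @param content_scale mitochondrial content of the second group relative
#'   to the first (default 0.5).
#' @param ... passed to [generatorConfig()].
#' @return a `GeneratorConfig` whose expected MEF ratio is stored in
#'   `$expected_mef` (named per group).
#' @export
contentScalingConfig <- function(content_scale = 0.5, ...) {
  cfg <- generatorConfig(...)
  m <- cfg$frac_mito  # expected benign MEF: equal mean abundance per feature
  mef_b <- m
  mef_t <- content_scale * m / (content_scale * m + 1 - m)
  b <- cfg$benign
  t <- b
  t$content_scale <- content_scale
  # equal intrinsic flux per mito protein => wet-weight flux scales with
  # mito protein per mg wet = protein_ug_per_mg * MEF (protein factor equal)
  t$true_jo2 <- b$true_jo2 * (mef_t / mef_b)
  cfg$tumor <- t
  cfg$expected_mef <- c(benign = mef_b, tumor = mef_t)
  cfg
}

.lnormFactor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -s^2 / 2, s))
}

.stateFluxes <- function(gc, protocol) {
  states <- .protocolStates[[protocol]]
  j <- numeric(length(states))
  names(j) <- states
  for (s in states) {
    j[s] <- switch(s,
      OMY = (1 - gc$coupling_fraction) * gc$true_jo2[["PMDGS"]],
      AMA = gc$residual_fraction * gc$true_jo2[["PMDGS"]],
      AMA_ROT = gc$residual_fraction * gc$true_jo2[["PMDGS"]],
      gc$true_jo2[[s]])
  }
  j
}

#' Simulate a respirometry cohort
#'
#' Generates closed-chamber O2 traces for both groups of `config` under one
#' SUIT protocol. Each biological sample yields two technical-replicate
#' traces sharing the sample's true flux ladder (a multiplicative
#' between-sample factor with coefficient of variation `bio_cv`); within
#' each state segment O2 declines linearly with slope
#' `-JO2 * amount / (1000 * chamber_volume_ml)` uM/s plus i.i.d. Gaussian
#' noise of sd `noise_sd`. The oligomycin-state flux is
#' `(1 - coupling_fraction) * J_PMDGS` and the antimycin A + rotenone state
#' retains `residual_fraction * J_PMDGS`.
#'
#' @param config a [generatorConfig()].
#' @param protocol `"CI_CII"`, `"CI_CII_coupling"`, or `"LIPID"`.
#' @param seed RNG seed; defaults to `config$seed`.
#'
#' @return list of [RespirometryTrace-class] objects with attribute
#'   `truth`: a data.frame of per-sample true fluxes
#'   (`sample_id, group, state, jo2_true`).
#' @examples
#' traces <- simulateRespirometry(generatorConfig(), "CI_CII", seed = 7)
#' traces[[1]]
#' @export
simulateRespirometry <- function(config,
                                 protocol = c("CI_CII", "CI_CII_coupling",
                                              "LIPID"),
                                 seed = config$seed) {
  protocol <- match.arg(protocol)
  validateGeneratorConfig(config)
  set.seed(seed)
  states <- .protocolStates[[protocol]]
  evlab <- .protocolEvents[[protocol]]
  dur <- config$state_duration_s
  dt <- config$dt_s
  ev_times <- dur * seq_along(evlab)
  total <- dur * length(states)
  tgrid <- seq(0, total, by = dt)
  seg <- pmin(findInterval(tgrid, ev_times, left.open = TRUE) + 1L,
              length(states))
  traces <- list()
  truth <- list()
  for (g in c("benign", "tumor")) {
    gc <- config[[g]]
    fac <- .lnormFactor(gc$n_samples, gc$bio_cv)
    jbase <- .stateFluxes(gc, protocol)
    for (i in seq_len(gc$n_samples)) {
      sid <- sprintf("%s_%02d", g, i)
      jsamp <- jbase * fac[i]
      truth[[sid]] <- data.frame(sample_id = sid, group = g,
                                 state = states, jo2_true = unname(jsamp),
                                 row.names = NULL)
      slope <- -jsamp[seg] * gc$amount / (1000 * config$chamber_volume_ml)
      # integrate the piecewise-constant slope over the grid
      o2_clean <- config$start_o2 + c(0, cumsum(slope[-1] * diff(tgrid)))
      for (r in 1:2) {
        o2 <- o2_clean + stats::rnorm(length(tgrid), 0, gc$noise_sd)
        traces[[length(traces) + 1L]] <- RespirometryTrace(
          sampleId = sid, group = g, replicateId = r,
          time = tgrid, o2 = o2,
          events = data.frame(time_s = ev_times, label = evlab),
          chamberVolumeMl = config$chamber_volume_ml,
          amount = gc$amount, amountUnits = "mg_wet_weight")
      }
    }
  }
  attr(traces, "truth") <- do.call(rbind, truth)
  attr(traces, "protocol") <- protocol
  traces
}

.simAbundance <- function(config, n_per_group, annotation, dropout, seed,
                          layer) {
  nb <- n_per_group
  groups <- rep(c("benign", "tumor"), each = nb)
  samples <- sprintf("%s_%02d", groups, rep(seq_len(nb), 2))
  nf <- nrow(annotation)
  base <- stats::rnorm(nf, mean = 10, sd = 1.5)  # log2 baseline per feature
  shift <- matrix(0, nf, 2, dimnames = list(NULL, c("benign", "tumor")))
  for (g in c("benign", "tumor")) {
    gc <- config[[g]]
    shift[annotation$is_mito, g] <- log2(gc$content_scale) + gc$mito_log2fc
  }
  if (layer == "tpm") {
    # per-complex transcript shifts override the content-driven one for
    # OXPHOS subunits in the tumor group
    for (cx in names(config$complex_log2fc)) {
      sel <- annotation$complex == cx
      shift[sel, "tumor"] <- config$complex_log2fc[[cx]]
      shift[sel, "benign"] <- 0
    }
  }
  noise <- matrix(stats::rnorm(nf * length(samples), 0,
                               config$abundance_log2_sd), nf)
  vals <- 2^(base + shift[, groups] + noise)
  dimnames(vals) <- list(annotation$feature_id, samples)
  list(values = vals, groups = groups, samples = samples,
       true_log2fc = shift[, "tumor"] - shift[, "benign"])
}

.scaledAnnotation <- function(config) {
  n_mito <- round(config$frac_mito * config$n_features)
  n_ox <- sum(lengths(.oxphosGenes))
  if (n_mito < n_ox)
    stop("frac_mito * n_features must allow the ", n_ox,
         " built-in OXPHOS subunits")
  builtinFixtureAnnotation(nFillerMito = n_mito - n_ox,
                           nFillerNonMito = config$n_features - n_mito)
}

#' Simulate a label-free proteome
#'
#' Log-normal abundances per feature and sample; tumor mitochondrial
#' features are scaled by `content_scale` and shifted by `mito_log2fc`;
#' detection dropout is applied as an abundance-independent Bernoulli mask
#' per feature x sample (undetected values become `NA`).
#'
#' @inheritParams simulateRespirometry
#' @return an [AbundanceExperiment-class] (`layer = "protein"`) whose
#'   metadata carries `truth` (per-feature true log2 fold change
#'   tumor/benign) and `degenerate` (flag set when `frac_mito` is 0 or 1).
#' @export
simulateProteome <- function(config, seed = config$seed) {
  validateGeneratorConfig(config)
  if (config$n_features < 10) stop("n_features must be >= 10")
  degenerate <- config$frac_mito %in% c(0, 1)
  if (degenerate)
    warning("frac_mito of 0 or 1 gives a degenerate proteome; flagged in metadata")
  set.seed(seed)
  ann <- .scaledAnnotation(config)
  sim <- .simAbundance(config, config$n_samples_proteome, ann,
                       dropout = TRUE, seed = seed, layer = "protein")
  nf <- nrow(ann)
  drop_rate <- ifelse(sim$groups == "benign",
                      config$benign$detection_dropout_rate,
                      config$tumor$detection_dropout_rate)
  mask <- matrix(stats::runif(nf * length(sim$samples)), nf) >=
    rep(drop_rate, each = nf)
  vals <- sim$values
  vals[!mask] <- NA_real_
  AbundanceExperiment(vals, ann, group = sim$groups, layer = "protein",
                      detected = mask,
                      truth = data.frame(feature_id = ann$feature_id,
                                         true_log2fc = sim$true_log2fc),
                      degenerate = degenerate)
}

#' Simulate a bulk transcriptome (TPM)
#'
#' Log-normal expression with per-complex tumor shifts on the OXPHOS
#' subunit blocks, column-normalized to transcripts per million.
#'
#' @inheritParams simulateRespirometry
#' @return an [AbundanceExperiment-class] (`layer = "tpm"`); columns sum to
#'   1e6 within 1e-6 relative tolerance.
#' @export
simulateTranscriptome <- function(config, seed = config$seed) {
  validateGeneratorConfig(config)
  set.seed(seed)
  ann <- .scaledAnnotation(config)
  sim <- .simAbundance(config, config$n_samples_transcriptome, ann,
                       dropout = FALSE, seed = seed, layer = "tpm")
  tpm <- sweep(sim$values, 2, colSums(sim$values), "/") * 1e6
  AbundanceExperiment(tpm, ann, group = sim$groups, layer = "tpm",
                      truth = data.frame(feature_id = ann$feature_id,
                                         true_log2fc = sim$true_log2fc))
}

.atlasCellTypes <- c(cancer_epithelial = 0.25, normal_epithelial = 0.05,
                     T_cells = 0.25, CAFs = 0.15, myeloid = 0.12,
                     B_cells = 0.08, plasmablasts = 0.04,
                     endothelial = 0.04, PVL = 0.02)

.ifProportions <- list(
  benign = c(epithelial = 45, mesenchymal = 25, endothelial = 5,
             myeloid = 4, T_cells = 3, plasmablasts = 2),
  tumor = c(epithelial = 70, mesenchymal = 10, endothelial = 4,
            myeloid = 6, T_cells = 4, plasmablasts = 2)
)

#' Simulate cell-type expression and proportion tables
#'
#' Emulates (i) a single-cell-atlas summary: for each major cell type and
#' OXPHOS subunit gene, the percentage of cells of that type expressing the
#' gene, plus the cell-type proportions of the reference atlas (summing to
#' 1); and (ii) an immunofluorescence panel: percent immunopositive tissue
#' area per harmonized cell type and group (sums <= 100, overlap-free).
#'
#' @inheritParams simulateRespirometry
#' @param cell_types named numeric vector of atlas cell-type proportions
#'   (must sum to 1; at least 2 types).
#' @param if_proportions named list (per group) of named percent
#'   immunopositive-area vectors.
#' @return list with elements `expression` (data.frame `cell_type,
#'   gene_symbol, pct_expressing, scref_proportion`) and `proportions`
#'   (data.frame `group, cell_type, pct_immunopositive`).
#' @export
simulateCellTypeTables <- function(config, seed = config$seed,
                                   cell_types = .atlasCellTypes,
                                   if_proportions = .ifProportions) {
  if (length(cell_types) < 2)
    stop("at least 2 cell types are required")
  if (abs(sum(cell_types) - 1) > 1e-8)
    stop("atlas cell-type proportions must sum to 1")
  ifs <- unique(unlist(lapply(if_proportions, names)))
  set.seed(seed)
  genes <- unlist(.oxphosGenes, use.names = FALSE)
  # epithelial cells express OXPHOS subunits broadly; stromal/immune less so
  base_pct <- c(cancer_epithelial = 85, normal_epithelial = 80,
                T_cells = 45, CAFs = 55, myeloid = 50, B_cells = 40,
                plasmablasts = 60, endothelial = 55, PVL = 50)
  expr <- expand.grid(cell_type = names(cell_types), gene_symbol = genes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- ifelse(names(cell_types)[match(expr$cell_type, names(cell_types))] %in%
                 names(base_pct), base_pct[expr$cell_type], 50)
  expr$pct_expressing <- pmin(100, pmax(0,
    stats::rnorm(nrow(expr), mean = mu, sd = 10)))
  expr$scref_proportion <- unname(cell_types[expr$cell_type])
  props <- do.call(rbind, lapply(names(if_proportions), function(g) {
    p <- if_proportions[[g]]
    if (sum(p) > 100) stop(g, ": immunopositive areas must sum to <= 100")
    data.frame(group = g, cell_type = names(p), pct_immunopositive = unname(p),
               row.names = NULL)
  }))
  map <- defaultCellTypeMap()
  harmonized <- unique(map$harmonized[map$atlas %in% names(cell_types)])
  if (!length(intersect(harmonized, unique(props$cell_type))))
    stop("cell-type sets of the two tables do not intersect after harmonization")
  list(expression = expr, proportions = props)
}
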