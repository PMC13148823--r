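## The three flux normalization schemes: per mg wet weight (the raw scale of
## the state table), per ug total protein (group Bradford factor), and per
## mitochondrial content via the mitochondrial enrichment factor (MEF).

#' Mitochondrial enrichment factor (MEF)
#'
#' For each sample, the summed abundance of all detected mitochondrial
#' proteins divided by the summed abundance of the whole detected proteome:
#' `mef_s = sum(mito) / sum(all)`. Group values are the mean over the
#' group's samples. MEF is a unitless fraction in `[0, 1]` used to correct
#' flux for mitochondrial content.
#'
#' @param abundance an [AbundanceExperiment-class] with `layer = "protein"`;
#'   the mitochondrial flag is taken from `rowData(abundance)$is_mito`.
#' @return list with `per_sample` (named numeric) and `per_group` (named
#'   numeric of group means).
#' @examples
#' prot <- simulateProteome(generatorConfig(), seed = 1)
#' computeMEF(prot)$per_group
#' @export
computeMEF <- function(abundance) {
  if (abundanceLayer(abundance) != "protein")
    stop("MEF is defined on the protein layer")
  a <- assay(abundance, "abundance")
  mito <- rowData(abundance)$is_mito
  tot <- colSums(a, na.rm = TRUE)
  if (any(tot == 0))
    stop("sample(s) with zero total abundance: ",
         paste(colnames(a)[tot == 0], collapse = ", "))
  per_sample <- colSums(a[mito, , drop = FALSE], na.rm = TRUE) / tot
  grp <- sampleGroups(abundance)
  per_group <- vapply(split(per_sample, grp), mean, numeric(1))
  list(per_sample = per_sample, per_group = per_group)
}

#' Group total-protein factors from a Bradford table
#'
#' @param bradfordTable data.frame with columns `sample_id`, `group`,
#'   `wet_mg` (tissue mass assayed), `protein_ug` (total protein measured).
#' @return named numeric: group mean of per-sample `protein_ug / wet_mg`
#'   (ug total protein per mg wet weight).
#' @export
proteinFactor <- function(bradfordTable) {
  need <- c("sample_id", "group", "wet_mg", "protein_ug")
  if (!all(need %in% names(bradfordTable)))
    stop("bradford table needs columns: ", paste(need, collapse = ", "))
  if (any(bradfordTable$wet_mg <= 0))
    stop("wet_mg must be positive")
  if (any(bradfordTable$protein_ug < 0))
    stop("protein_ug must be non-negative")
  ratio <- bradfordTable$protein_ug / bradfordTable$wet_mg
  vapply(split(ratio, bradfordTable$group), mean, numeric(1))
}

#' Bundle per-group normalization factors
#'
#' @param protein_ug_per_mg named numeric, ug total protein per mg wet
#'   weight per group (from [proteinFactor()]).
#' @param mef named numeric, group MEF in `[0, 1]` (from
#'   [computeMEF()]`$per_group`).
#' @return list of class `NormalizationFactors`.
#' @export
normalizationFactors <- function(protein_ug_per_mg, mef) {
  if (any(protein_ug_per_mg <= 0))
    stop("protein_ug_per_mg must be positive")
  if (any(mef < 0 | mef > 1))
    stop("mef must lie in [0, 1]")
  structure(list(protein_ug_per_mg = protein_ug_per_mg, mef = mef),
            class = "NormalizationFactors")
}

#' Apply a normalization scheme to a flux state table
#'
#' `wet_weight` passes the per-mg values through unchanged; `total_protein`
#' divides by the sample's group `protein_ug_per_mg` (units become
#' pmol s-1 per ug protein); `mef` further divides the total-protein value
#' by the group MEF, so the scheme algebra
#' `mef-normalized = total-protein-normalized / MEF` holds exactly. Within a
#' group every scheme is a positive scalar, so sample rank order is
#' preserved.
#'
#' @param stateTable a flux state table ([buildStateTable()] or
#'   [calibrateH2O2()]) on the wet-weight scale.
#' @param scheme `"wet_weight"`, `"total_protein"`, or `"mef"`.
#' @param factors a [normalizationFactors()] object (not needed for
#'   `wet_weight`).
#' @return the state table with rescaled `jo2` and updated `scheme` and
#'   `units` columns.
#' @export
applyNormalization <- function(stateTable,
                               scheme = c("wet_weight", "total_protein", "mef"),
                               factors = NULL) {
  scheme <- match.arg(scheme)
  if (!is.null(stateTable$scheme) &&
      any(stateTable$scheme != "wet_weight"))
    stop("state table must be on the wet_weight scale")
  analyte <- if (!is.null(stateTable$analyte)) stateTable$analyte[1] else "O2"
  if (scheme == "wet_weight") return(stateTable)
  if (is.null(factors))
    stop("factors required for scheme '", scheme, "'")
  pf <- factors$protein_ug_per_mg[stateTable$group]
  if (anyNA(pf))
    stop("missing protein factor for group(s): ",
         paste(setdiff(unique(stateTable$group),
                       names(factors$protein_ug_per_mg)), collapse = ", "))
  out <- stateTable
  out$jo2 <- stateTable$jo2 / pf
  out$units <- sprintf("pmol_%s_s-1_ug_protein-1", analyte)
  if (scheme == "mef") {
    mef <- factors$mef[stateTable$group]
    if (anyNA(mef))
      stop("missing MEF for group(s): ",
           paste(setdiff(unique(stateTable$group), names(factors$mef)),
                 collapse = ", "))
    if (any(mef == 0)) stop("group MEF of 0 cannot normalize")
    out$jo2 <- out$jo2 / mef
    out$units <- sprintf("pmol_%s_s-1_ug_protein-1_mef-1", analyte)
  }
  out$scheme <- scheme
  out
}

#' Calibrate H2O2 emission rates from fluorescence kinetics
#'
#' Fits the linear standard curve fluorescence = a + b * [H2O2] by ordinary
#' least squares, converts each sample's fluorescence time series to
#' concentration, takes the OLS slope of concentration versus time (uM/s),
#' and converts to a specific emission rate
#' `J_H2O2 = slope * volume_ml * 1000 / amount` (pmol H2O2 s-1 per mg).
#' The result is a flux state table with `analyte = "H2O2"` on the
#' wet-weight scale, to which [applyNormalization()] applies unchanged.
#'
#' @param fluorescenceTable data.frame with columns `sample_id`, `group`,
#'   `time_s`, `fluorescence_au`, `volume_ml`, `amount` (mg; constant
#'   within sample), and optionally `state` (default `"S"` for
#'   succinate-supported emission).
#' @param standardCurveTable data.frame with columns `conc_uM`,
#'   `fluorescence_au`; at least two distinct concentrations.
#' @return data.frame in the flux-state-table layout (`analyte = "H2O2"`,
#'   `scheme = "wet_weight"`).
#' @export
calibrateH2O2 <- function(fluorescenceTable, standardCurveTable) {
  sc <- standardCurveTable
  if (length(unique(sc$conc_uM)) < 2)
    stop("standard curve needs at least 2 distinct concentrations")
  cal <- stats::lm(fluorescence_au ~ conc_uM, data = sc)
  b <- stats::coef(cal)[["conc_uM"]]
  a <- stats::coef(cal)[["(Intercept)"]]
  if (b == 0) stop("singular calibration: flat standard curve")
  ft <- fluorescenceTable
  if (is.null(ft$state)) ft$state <- "S"
  out <- lapply(split(ft, ft$sample_id), function(d) {
    conc <- (d$fluorescence_au - a) / b
    slope <- stats::lm.fit(cbind(1, d$time_s), conc)$coefficients[2L]
    data.frame(sample_id = d$sample_id[1L], group = d$group[1L],
               state = d$state[1L],
               jo2 = unname(slope * d$volume_ml[1L] * 1000 / d$amount[1L]),
               n_replicates = 1L, analyte = "H2O2", scheme = "wet_weight",
               units = "pmol_H2O2_s-1_mg-1", row.names = NULL)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
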