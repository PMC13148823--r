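#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

## Event / state vocabulary of the SUIT protocols --------------------------

#' Injection-event vocabulary
#'
#' Valid labels for titration events in a respirometry trace: `E` endogenous
#' (implicit pre-injection state), `PM` pyruvate+malate, `D` ADP, `G`
#' glutamate, `S` succinate, `PC` palmitoyl-carnitine, `M` malate, `CC`
#' cytochrome c, `OMY` oligomycin, `AMA` antimycin A, `ROT` rotenone.
#'
#' @return Character vector of valid event labels.
#' @export
eventVocabulary <- function() {
  c("E", "PM", "D", "G", "S", "PC", "M", "CC", "OMY", "AMA", "ROT")
}

.inhibitorLabels <- function() c("OMY", "AMA", "ROT")

.validGroups <- c("benign", "tumor", "control", "treated")

## RespirometryTrace --------------------------------------------------------

#' RespirometryTrace: an annotated O2 concentration time series
#'
#' Holds one technical-replicate trace from a closed-chamber oxygraph:
#' chamber O2 concentration over time, the ordered injection events of the
#' SUIT protocol, and the sample metadata needed to convert an O2 slope into
#' a mass- or cell-specific flux.
#'
#' @slot sampleId character scalar, biological sample identifier.
#' @slot group character scalar, one of `benign`, `tumor`, `control`,
#'   `treated`.
#' @slot replicateId integer scalar, technical replicate number.
#' @slot time numeric vector, seconds, strictly increasing.
#' @slot o2 numeric vector, chamber O2 concentration in uM (= nmol/ml),
#'   same length as `time`.
#' @slot events data.frame with columns `time_s` (numeric, ordered) and
#'   `label` (character, from [eventVocabulary()]).
#' @slot chamberVolumeMl positive numeric scalar, chamber volume in ml.
#' @slot amount positive numeric scalar, tissue mass (mg wet weight) or
#'   number of cells (millions) in the chamber.
#' @slot amountUnits character scalar, `mg_wet_weight` or `million_cells`.
#'
#' @export
setClass("RespirometryTrace",
  representation(
    sampleId = "character",
    group = "character",
    replicateId = "integer",
    time = "numeric",
    o2 = "numeric",
    events = "data.frame",
    chamberVolumeMl = "numeric",
    amount = "numeric",
    amountUnits = "character"
  )
)

setValidity("RespirometryTrace", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || !nzchar(object@sampleId))
    msg <- c(msg, "sampleId must be a non-empty character scalar")
  if (length(object@group) != 1L || !(object@group %in% .validGroups))
    msg <- c(msg, sprintf("group must be one of: %s",
                          paste(.validGroups, collapse = ", ")))
  n <- length(object@time)
  if (length(object@o2) != n)
    msg <- c(msg, "time and o2 must have equal length")
  if (n >= 2L && any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  if (any(!is.finite(object@o2)))
    msg <- c(msg, "o2 values must be finite")
  ev <- object@events
  if (!all(c("time_s", "label") %in% names(ev)))
    msg <- c(msg, "events must have columns time_s and label")
  else {
    bad <- setdiff(ev$label, eventVocabulary())
    if (length(bad))
      msg <- c(msg, sprintf("unknown event label(s): %s",
                            paste(unique(bad), collapse = ", ")))
    if (nrow(ev) >= 2L && any(diff(ev$time_s) < 0))
      msg <- c(msg, "events must be time-ordered")
  }
  if (length(object@chamberVolumeMl) != 1L || !is.finite(object@chamberVolumeMl) ||
      object@chamberVolumeMl <= 0)
    msg <- c(msg, "chamberVolumeMl must be a positive scalar")
  if (length(object@amount) != 1L || !is.finite(object@amount) ||
      object@amount <= 0)
    msg <- c(msg, "amount must be a positive scalar")
  if (!(object@amountUnits %in% c("mg_wet_weight", "million_cells")))
    msg <- c(msg, "amountUnits must be mg_wet_weight or million_cells")
  if (length(msg)) msg else TRUE
})

#' Construct a RespirometryTrace
#'
#' @param sampleId biological sample identifier.
#' @param group group label (`benign`, `tumor`, `control`, `treated`).
#' @param replicateId technical replicate number.
#' @param time numeric vector of times (s), strictly increasing.
#' @param o2 numeric vector of O2 concentrations (uM).
#' @param events data.frame with columns `time_s`, `label`.
#' @param chamberVolumeMl chamber volume (ml); the instrument default is 2 ml.
#' @param amount tissue mass (mg wet weight) or million cells loaded.
#' @param amountUnits `"mg_wet_weight"` or `"million_cells"`.
#'
#' @return A validated [RespirometryTrace-class] object.
#' @examples
#' tr <- RespirometryTrace("s1", "benign", 1, time = 0:99,
#'   o2 = 180 - 0.05 * (0:99),
#'   events = data.frame(time_s = numeric(), label = character()),
#'   amount = 18)
#' tr
#' @export
RespirometryTrace <- function(sampleId, group, replicateId = 1L,
                              time, o2, events,
                              chamberVolumeMl = 2, amount,
                              amountUnits = "mg_wet_weight") {
  new("RespirometryTrace",
      sampleId = as.character(sampleId), group = as.character(group),
      replicateId = as.integer(replicateId),
      time = as.numeric(time), o2 = as.numeric(o2),
      events = data.frame(time_s = as.numeric(events$time_s),
                          label = as.character(events$label)),
      chamberVolumeMl = as.numeric(chamberVolumeMl),
      amount = as.numeric(amount), amountUnits = amountUnits)
}

setMethod("show", "RespirometryTrace", function(object) {
  cat("RespirometryTrace:", object@sampleId,
      sprintf("(%s, replicate %d)\n", object@group, object@replicateId))
  cat(sprintf("  %d points over %.0f s; O2 %.1f -> %.1f uM\n",
              length(object@time), diff(range(object@time)),
              object@o2[1L], object@o2[length(object@o2)]))
  cat(sprintf("  %d events: %s\n", nrow(object@events),
              paste(object@events$label, collapse = " ")))
  cat(sprintf("  %.3g %s in %.1f ml chamber\n", object@amount,
              object@amountUnits, object@chamberVolumeMl))
})

## Accessors ---------------------------------------------------------------

#' @describeIn RespirometryTrace sample identifier
#' @param object,x a `RespirometryTrace`
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname RespirometryTrace-class
#' @export
setMethod("sampleId", "RespirometryTrace", function(object) object@sampleId)

#' @rdname RespirometryTrace-class
#' @export
setGeneric("traceEvents", function(object) standardGeneric("traceEvents"))

#' @rdname RespirometryTrace-class
#' @export
setMethod("traceEvents", "RespirometryTrace", function(object) object@events)

#' @rdname RespirometryTrace-class
#' @export
setGeneric("traceGroup", function(object) standardGeneric("traceGroup"))

#' @rdname RespirometryTrace-class
#' @export
setMethod("traceGroup", "RespirometryTrace", function(object) object@group)

## AbundanceExperiment ------------------------------------------------------

#' AbundanceExperiment: an annotated omics abundance matrix
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' subclass holding one omics layer (label-free protein abundance or TPM)
#' with a `detected` mask and a MitoCarta-style feature annotation in
#' `rowData` (`gene_symbol`, `is_mito`, `complex`, `pathway`).
#'
#' The `protein` layer permits missing (undetected) values; the `tpm` layer
#' does not, and its columns must each sum to 1e6 within 1e-6 relative
#' tolerance.
#'
#' @export
setClass("AbundanceExperiment", contains = "SummarizedExperiment")

setValidity("AbundanceExperiment", function(object) {
  msg <- character()
  layer <- metadata(object)$layer
  if (is.null(layer) || !(layer %in% c("protein", "tpm")))
    return("metadata(object)$layer must be 'protein' or 'tpm'")
  if (!all(c("abundance", "detected") %in% names(assays(object))))
    return("assays must include 'abundance' and 'detected'")
  need <- c("gene_symbol", "is_mito", "complex")
  if (!all(need %in% names(rowData(object))))
    msg <- c(msg, sprintf("rowData must contain: %s", paste(need, collapse = ", ")))
  else {
    cx <- rowData(object)$complex
    bad <- setdiff(unique(cx), c("CI", "CII", "CIII", "CIV", "CV", "none"))
    if (length(bad))
      msg <- c(msg, sprintf("invalid complex value(s): %s", paste(bad, collapse = ", ")))
    if (any(cx != "none" & !rowData(object)$is_mito))
      msg <- c(msg, "complex != 'none' requires is_mito = TRUE")
  }
  if (!("group" %in% names(colData(object))))
    msg <- c(msg, "colData must contain a 'group' column")
  a <- assay(object, "abundance")
  if (any(a[!is.na(a)] < 0))
    msg <- c(msg, "abundance values must be non-negative")
  if (layer == "tpm") {
    if (anyNA(a))
      msg <- c(msg, "tpm layer does not permit missing values")
    else {
      cs <- colSums(a)
      if (any(abs(cs - 1e6) > 1e-6 * 1e6 + 1e-6))
        msg <- c(msg, "tpm columns must sum to 1e6 within 1e-6 relative tolerance")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AbundanceExperiment
#'
#' @param abundance numeric matrix (features x samples), non-negative;
#'   `NA` marks undetected values (protein layer only).
#' @param annotation data.frame with columns `feature_id`, `gene_symbol`,
#'   `is_mito`, `complex` (and optionally `pathway`), one row per feature of
#'   `abundance` (matched by `feature_id` against rownames).
#' @param group character vector of per-sample group labels.
#' @param layer `"protein"` or `"tpm"`.
#' @param detected optional logical matrix; defaults to `!is.na(abundance)`.
#' @param ... extra metadata entries (e.g. ground-truth tables from the
#'   simulators).
#'
#' @return An [AbundanceExperiment-class].
#' @export
AbundanceExperiment <- function(abundance, annotation, group,
                                layer = c("protein", "tpm"),
                                detected = NULL, ...) {
  layer <- match.arg(layer)
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)))
    stop("abundance must have feature rownames")
  idx <- match(rownames(abundance), annotation$feature_id)
  if (anyNA(idx))
    stop("annotation does not cover all features of the abundance matrix")
  annotation <- annotation[idx, , drop = FALSE]
  if (is.null(detected)) detected <- !is.na(abundance)
  rd <- DataFrame(gene_symbol = annotation$gene_symbol,
                  is_mito = annotation$is_mito,
                  complex = annotation$complex,
                  pathway = if (!is.null(annotation$pathway))
                    annotation$pathway else rep("", nrow(annotation)),
                  row.names = rownames(abundance))
  se <- SummarizedExperiment(
    assays = list(abundance = abundance, detected = detected),
    rowData = rd,
    colData = DataFrame(group = as.character(group),
                        row.names = colnames(abundance)))
  metadata(se) <- c(list(layer = layer), list(...))
  new("AbundanceExperiment", se)
}

#' @describeIn AbundanceExperiment the omics layer ("protein" or "tpm")
#' @param object an `AbundanceExperiment`
#' @export
setGeneric("abundanceLayer", function(object) standardGeneric("abundanceLayer"))

#' @rdname AbundanceExperiment-class
#' @export
setMethod("abundanceLayer", "AbundanceExperiment",
          function(object) metadata(object)$layer)

#' @rdname AbundanceExperiment-class
#' @export
setGeneric("sampleGroups", function(object) standardGeneric("sampleGroups"))

#' @rdname AbundanceExperiment-class
#' @export
setMethod("sampleGroups", "AbundanceExperiment",
          function(object) setNames(colData(object)$group, colnames(object)))
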