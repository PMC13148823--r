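## Cell-type-weighted OXPHOS mRNA Index and Total OXPHOS mRNA Score:
## atlas percent-expression per complex, weighted by reference cell-type
## proportion, multiplied by the immunopositive tissue area of the cell
## type, summed over the five complexes.

#' Default atlas-to-tissue cell-type harmonization map
#'
#' Maps the major cell types of a breast single-cell reference atlas onto
#' the coarser panel resolvable by tissue immunofluorescence: cancer and
#' normal epithelial collapse to `epithelial`; cancer-associated
#' fibroblasts (CAFs) and perivascular-like cells (PVL) to `mesenchymal`;
#' B cells have no marker in the panel and are unmapped.
#'
#' @return data.frame with columns `atlas`, `harmonized` (editable; pass
#'   your own to [collapseCellTypes()]).
#' @export
defaultCellTypeMap <- function() {
  data.frame(
    atlas = c("cancer_epithelial", "normal_epithelial", "CAFs", "PVL",
              "T_cells", "myeloid", "plasmablasts", "endothelial"),
    harmonized = c("epithelial", "epithelial", "mesenchymal", "mesenchymal",
                   "T_cells", "myeloid", "plasmablasts", "endothelial"),
    stringsAsFactors = FALSE)
}

#' Proportion-weighted percent expression per complex
#'
#' For each cell type and respiratory complex, averages the percentage of
#' cells expressing each subunit gene of the complex, then multiplies by
#' the cell type's proportion in the reference atlas:
#' `%Expression_CT(t, c) = mean_g pct_expressing(t, g) * scref_proportion(t)`.
#' Genes missing a complex assignment are dropped with a message.
#'
#' @param summary data.frame `cell_type, gene_symbol, pct_expressing,
#'   scref_proportion` (see [simulateCellTypeTables()]).
#' @param annotation feature annotation mapping `gene_symbol` to `complex`
#'   (default [builtinFixtureAnnotation()]).
#' @return data.frame `cell_type, complex, expression_ct`.
#' @export
weightedPctExpression <- function(summary,
                                  annotation = builtinFixtureAnnotation()) {
  cx <- annotation$complex[match(tolower(summary$gene_symbol),
                                 tolower(annotation$gene_symbol))]
  unmapped <- is.na(cx) | cx == "none"
  if (any(unmapped)) {
    message(sum(unmapped), " summary row(s) with genes not mapped to a ",
            "complex were dropped: ",
            paste(utils::head(unique(summary$gene_symbol[unmapped]), 5),
                  collapse = ", "))
    summary <- summary[!unmapped, , drop = FALSE]
    cx <- cx[!unmapped]
  }
  if (!nrow(summary)) stop("no genes mapped to any complex")
  key <- interaction(summary$cell_type, cx, drop = FALSE)
  mean_pct <- tapply(summary$pct_expressing, list(summary$cell_type, cx),
                     mean)
  complexes <- c("CI", "CII", "CIII", "CIV", "CV")
  if (!all(complexes %in% colnames(mean_pct)))
    stop("complex(es) with zero mapped genes: ",
         paste(setdiff(complexes, colnames(mean_pct)), collapse = ", "))
  prop <- tapply(summary$scref_proportion, summary$cell_type, unique)
  out <- expand.grid(cell_type = rownames(mean_pct), complex = complexes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$expression_ct <- as.numeric(mean_pct[cbind(out$cell_type, out$complex)]) *
    as.numeric(unlist(prop)[out$cell_type])
  out
}

#' Collapse atlas cell types to the tissue panel
#'
#' Sums the proportion-weighted `%Expression_CT` of atlas cell types that
#' map to the same harmonized tissue cell type (the proportion weights make
#' the sum the natural pooled value). Atlas types absent from the map are
#' dropped with a message.
#'
#' @param exprCt output of [weightedPctExpression()].
#' @param map data.frame `atlas, harmonized` (default
#'   [defaultCellTypeMap()]).
#' @return data.frame `cell_type, complex, expression_ct` on harmonized
#'   types.
#' @export
collapseCellTypes <- function(exprCt, map = defaultCellTypeMap()) {
  h <- map$harmonized[match(exprCt$cell_type, map$atlas)]
  if (anyNA(h)) {
    message("atlas cell type(s) without harmonized mapping dropped: ",
            paste(unique(exprCt$cell_type[is.na(h)]), collapse = ", "))
    exprCt <- exprCt[!is.na(h), , drop = FALSE]
    h <- h[!is.na(h)]
  }
  agg <- stats::aggregate(expression_ct ~ cell_type + complex,
                          data = transform(exprCt, cell_type = h), FUN = sum)
  agg[order(agg$cell_type, agg$complex), ]
}

#' OXPHOS mRNA Index
#'
#' Per group, cell type, and complex, the literal product of the two
#' percent-scale quantities:
#' `Index = %Expression_CT * %Immunopositive_CT` (units % x %; the index
#' ranks cell-type contributions and is not rescaled). Cell types are
#' inner-joined between the two tables; dropped types are messaged.
#'
#' @param exprCt data.frame `cell_type, complex, expression_ct`
#'   (harmonized; see [collapseCellTypes()]).
#' @param proportions data.frame `group, cell_type, pct_immunopositive`.
#' @return data.frame `group, cell_type, complex, index`.
#' @export
oxphosIndex <- function(exprCt, proportions) {
  common <- intersect(unique(exprCt$cell_type),
                      unique(proportions$cell_type))
  if (!length(common)) stop("no cell types shared between the two tables")
  dropped <- setdiff(union(unique(exprCt$cell_type),
                           unique(proportions$cell_type)), common)
  if (length(dropped))
    message("cell type(s) present in only one table dropped: ",
            paste(dropped, collapse = ", "))
  e <- exprCt[exprCt$cell_type %in% common, ]
  p <- proportions[proportions$cell_type %in% common, ]
  out <- merge(e, p, by = "cell_type")
  out$index <- out$expression_ct * out$pct_immunopositive
  res <- out[order(out$group, out$cell_type, out$complex),
             c("group", "cell_type", "complex", "index")]
  rownames(res) <- NULL
  res
}

#' Total OXPHOS mRNA Score
#'
#' Sums the OXPHOS mRNA Index over the five complexes CI..CV for each
#' (group, cell type); all five complexes must be present.
#'
#' @param indexTable output of [oxphosIndex()].
#' @return data.frame `group, cell_type, total_score`.
#' @export
totalScore <- function(indexTable) {
  counts <- table(indexTable$group, indexTable$cell_type)
  n_cx <- tapply(indexTable$complex,
                 list(indexTable$group, indexTable$cell_type),
                 function(x) length(unique(x)))
  if (any(!is.na(n_cx) & n_cx < 5))
    stop("missing complex rows for some (group, cell type)")
  agg <- stats::aggregate(index ~ group + cell_type, data = indexTable,
                          FUN = sum)
  names(agg)[names(agg) == "index"] <- "total_score"
  agg[order(agg$group, agg$cell_type), ]
}
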