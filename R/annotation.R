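## OXPHOS complex subunit gene lists (mouse symbols), as used for the
## per-complex transcript summaries. Ndufa4 sits with Complex IV: it is a
## COX-associated subunit despite the legacy Nduf name.

.oxphosGenes <- list(
  CI = c("Ndufa1", "Ndufa10", "Ndufa11", "Ndufa12", "Ndufa13", "Ndufa2",
         "Ndufa3", "Ndufa5", "Ndufa6", "Ndufa7", "Ndufa8", "Ndufa9",
         "Ndufab1", "Ndufb10", "Ndufb11", "Ndufb2", "Ndufb3", "Ndufb4",
         "Ndufb5", "Ndufb6", "Ndufb7", "Ndufb8", "Ndufb9", "Ndufc1",
         "Ndufc2", "Ndufs1", "Ndufs2", "Ndufs3", "Ndufs4", "Ndufs5",
         "Ndufs6", "Ndufs7", "Ndufs8", "Ndufv1", "Ndufv2", "Ndufv3"),
  CII = c("Sdha", "Sdhb", "Sdhc", "Sdhd"),
  CIII = c("Cyc1", "Uqcr10", "Uqcr11", "Uqcrb", "Uqcrc1", "Uqcrc2",
           "Uqcrfs1", "Uqcrh", "Uqcrq"),
  CIV = c("Cox4i1", "Cox4i2", "Cox5a", "Cox5b", "Cox6a1", "Cox6b1",
          "Cox6b2", "Cox6c", "Cox7a1", "Cox7a2", "Cox7a2l", "Cox7b",
          "Cox7c", "Cox8a", "Cox8b", "Ndufa4"),
  CV = c("Atp5a1", "Atp5b", "Atp5c1", "Atp5d", "Atp5e", "Atp5g1",
         "Atp5g2", "Atp5g3", "Atp5h", "Atp5j", "Atp5j2", "Atp5k",
         "Atp5l", "Atp5md", "Atp5mpl", "Atp5o", "Atp5pb", "Atpif1",
         "Dmac2l")
)

#' Built-in OXPHOS/mitochondrial feature annotation
#'
#' A MitoCarta-style feature annotation shipping the OXPHOS complex subunit
#' gene lists (36 Complex I, 4 Complex II, 9 Complex III, 16 Complex IV
#' including Ndufa4, 19 Complex V / ATP synthase genes), all flagged
#' mitochondrial, plus configurable filler features: generic mitochondrial
#' proteins with no complex assignment and non-mitochondrial background
#' proteins.
#'
#' @param nFillerMito number of filler mitochondrial features (complex
#'   `"none"`, pathway `"mito_other"`).
#' @param nFillerNonMito number of filler non-mitochondrial features.
#'
#' @return data.frame with columns `feature_id`, `gene_symbol`, `is_mito`,
#'   `complex` (`CI`..`CV` or `none`), `pathway`.
#' @examples
#' ann <- builtinFixtureAnnotation()
#' table(ann$complex)
#' @export
builtinFixtureAnnotation <- function(nFillerMito = 100, nFillerNonMito = 400) {
  ox <- data.frame(
    feature_id = unlist(.oxphosGenes, use.names = FALSE),
    gene_symbol = unlist(.oxphosGenes, use.names = FALSE),
    is_mito = TRUE,
    complex = rep(names(.oxphosGenes), lengths(.oxphosGenes)),
    pathway = "oxphos",
    stringsAsFactors = FALSE
  )
  filler <- function(prefix, n, mito, pathway) {
    if (n == 0L) return(NULL)
    id <- sprintf("%s%03d", prefix, seq_len(n))
    data.frame(feature_id = id, gene_symbol = id, is_mito = mito,
               complex = "none", pathway = pathway, stringsAsFactors = FALSE)
  }
  ann <- rbind(ox,
               filler("Mito", nFillerMito, TRUE, "mito_other"),
               filler("Gene", nFillerNonMito, FALSE, "other"))
  rownames(ann) <- NULL
  ann
}
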