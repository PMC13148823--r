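# mitoflux

Bioenergetic analysis of tissue respirometry with mitochondrial-content
normalization and multi-omic OXPHOS integration.

## The problem

High-resolution respirometry reports oxygen flux per mg of tissue, but a
per-mg flux confounds tissue composition with mitochondrial function. A
tumor that has *down*regulated its mitochondrial proteome can still respire
several-fold faster per mg than benign tissue — and deciding whether that
reflects more mitochondria or intrinsically activated OXPHOS requires
renormalizing flux from wet weight, to total protein, to mitochondrial
protein. `mitoflux` is for researchers running substrate–uncoupler–inhibitor
titration (SUIT) protocols on permeabilized tissue alongside quantitative
proteomics/transcriptomics who need that chain as tested, reusable code.

## What it computes

**Flux extraction.** For each titration state (composite labels
`E → PM → PMD → PMDG → PMDGS`, inhibitor states `OMY`, `AMA_ROT`), the
steady-state flux is the OLS slope of chamber O2 over a post-injection
window:

    JO2 = -d[O2]/dt × V_chamber(ml) × 1000 / amount   [pmol O2 s⁻¹ mg⁻¹]

Technical replicates are pooled by mean; coupling is summarized as
`100·(1 − J_OMY/J_PMDGS)` (oligomycin-sensitive share),
plus the antimycin A + rotenone residual and the cytochrome c response.

**Three-way normalization.** Fluxes per mg wet weight, per µg total protein
(group Bradford factor), and per mitochondrial content via the
mitochondrial enrichment factor

    MEF_s = Σ mito protein abundance(s) / Σ total protein abundance(s)

computed per sample from a MitoCarta-style-annotated proteome and averaged
per group; `mef`-normalized = `total_protein`-normalized / MEF, exactly.
H2O2 emission rates (standard-curve calibrated) flow through the same
schemes.

**Omics.** Detection sets (detected in ≥ k samples per group), a Welch-t +
BH differential-abundance stand-in (significance at padj < 0.1), summed
mitochondrial abundance, per-complex OXPHOS subunit summaries (CI–CV,
against mito or total denominator), and transcriptome–proteome log2FC
integration (Pearson r, co-directional significant overlaps).

**Cell-type OXPHOS scoring.** Per cell type and complex,
`Index = %Expression_CT × %Immunopositive_CT`, where `%Expression_CT` is
the atlas-proportion-weighted mean percent of cells expressing the
complex's subunits and `%Immunopositive_CT` is the cell type's percent
tissue area by immunofluorescence; `Total Score = Σ_{CI..CV} Index`.

**Statistics.** Welch/Student t, Cohen's d, CV%, Benjamini–Hochberg FDR,
and two-sample two-sided power from the noncentral t distribution
(`df = 2n−2`, `ncp = d·√(n/2)`).

Every estimator is validated against a built-in synthetic-cohort generator
with exact ground truth (flux ladders, coupling fractions, content scaling,
dropout masks, cell-type tables).

## Worked example

```r
library(mitoflux)

cfg    <- generatorConfig()                       # benign vs tumor presets
traces <- simulateRespirometry(cfg, "CI_CII_coupling", seed = 42)
states <- buildStateTable(traces)                 # per-state JO2, replicates pooled
head(states[states$state == "PMDGS", c("sample_id","group","state","jo2","units")], 4)
#>    sample_id  group state      jo2            units
#> 5  benign_01 benign PMDGS 7.130650 pmol_O2_s-1_mg-1
#> 13 benign_02 benign PMDGS 3.900640 pmol_O2_s-1_mg-1
#> 21 benign_03 benign PMDGS 5.210024 pmol_O2_s-1_mg-1
#> 29 benign_04 benign PMDGS 5.780418 pmol_O2_s-1_mg-1

prot <- simulateProteome(cfg, seed = 42)          # annotated label-free proteome
mef  <- computeMEF(prot)$per_group                # mito share of total proteome
round(mef, 4)
#> benign  tumor
#> 0.1462 0.0743

factors <- normalizationFactors(c(benign = 80, tumor = 100), mef = mef)
mtab    <- applyNormalization(states, "mef", factors)
round(tapply(states$jo2[states$state=="PMDGS"], states$group[states$state=="PMDGS"], mean), 2)
#> benign  tumor
#>   5.80  38.83        # wet weight: ~6.7-fold higher in tumor
round(tapply(mtab$jo2[mtab$state=="PMDGS"], mtab$group[mtab$state=="PMDGS"], mean), 4)
#> benign  tumor
#> 0.4959 5.2298        # per mito protein: the difference survives (intrinsic)

cm <- couplingMetrics(states)
round(tapply(cm$omy_inhibition_pct, cm$group, median), 1)
#> benign  tumor
#>   55.1   80.4        # tumors are MORE coupled, not uncoupled
```

Read: tumors respire ~7× faster per mg despite having half the
mitochondrial protein share (MEF 0.074 vs 0.146); after MEF normalization
the difference persists (~10×), so it is intrinsic, and the higher
oligomycin sensitivity (80% vs 55%) rules out uncoupling as the cause.

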