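---
title: "Methods: respirometry flux extraction, content normalization, and multi-omic OXPHOS scoring"
author: "mitoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: respirometry flux extraction, content normalization, and multi-omic OXPHOS scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoflux)
```

# The scientific problem

In fully differentiated tissues, respiratory capacity usually tracks
mitochondrial content: more mitochondria, more oxygen flux. Tumors can break
this relationship. A tissue may downregulate its mitochondrial proteome yet
respire at several-fold higher rates per milligram, which implies an
*intrinsic* activation of oxidative phosphorylation (OXPHOS) rather than a
content change. Distinguishing the two requires measuring oxygen flux in a
way that can be renormalized from "per mg of tissue" to "per unit of
mitochondrial protein" — and that renormalization requires integrating
high-resolution respirometry with quantitative proteomics.

`mitoflux` implements that analysis chain end to end:

1. **Flux extraction** from closed-chamber respirometry traces recorded
   under a substrate–uncoupler–inhibitor titration (SUIT) protocol.
2. **Three-way normalization** of those fluxes: per mg wet weight, per µg
   total protein, and per mitochondrial content via the *mitochondrial
   enrichment factor* (MEF).
3. **Omics support**: detection sets, a simple differential-abundance
   stand-in, per-complex OXPHOS subunit summaries, and
   transcriptome–proteome fold-change integration.
4. **Cell-type attribution** of the bulk OXPHOS transcriptome through a
   cell-type-weighted OXPHOS mRNA Index and Total Score.
5. **Design statistics**: Welch/Student t, Cohen's d, CV, BH-FDR, and
   noncentral-t power.

Because the deposited datasets of any particular study are not required to
exercise this machinery, the package ships a synthetic-cohort generator
with exact ground truth; every estimator is validated against it.

# Flux extraction from SUIT traces

A trace is the chamber O2 concentration (µM, i.e. nmol/ml) sampled over
time with a record of injection events. Within each titration state the
oxygen decline is approximately linear, so the steady-state flux is taken
as the ordinary-least-squares slope over an analysis window:

$$ J_{O_2} = -\,\frac{d[O_2]}{dt} \cdot \frac{V_\mathrm{chamber}\ \mathrm{(ml)} \cdot 1000}{\mathrm{amount}} \quad \left[\mathrm{pmol\ O_2\ s^{-1}\ mg^{-1}}\right] $$

with consumption positive. Negative fitted fluxes (possible in
near-zero-flux inhibitor states under noise) are retained, not clamped, so
that downstream group statistics see the full noise structure.

**Windows.** Instrument vendors do not agree on stabilization times, and
steady-state windows are rarely reported explicitly; we therefore declare
them: each window starts `discard_s = 30` s after the injection (mixing and
re-equilibration) and spans at most `window_s = 60` s, truncated at the
next event. Both are arguments of `segmentStates()` and
`buildStateTable()`. A state whose inter-event interval is shorter than the
discard is *flagged missing*, never silently dropped. OLS on the raw
window is used rather than any vendor-style slope smoothing.

**Composite state labels** accumulate substrate additions — `E`
(endogenous), `PM` (pyruvate + malate), `PMD` (+ADP), `PMDG` (+glutamate),
`PMDGS` (+succinate, maximal CI+CII-supported respiration), with
cytochrome c appending `C` (`PMDGSC`). An inhibitor restarts the label:
`OMY` after oligomycin, `AMA` after antimycin A, and `AMA_ROT` once
rotenone follows antimycin A. This keeps the table vocabulary aligned with
how respirometry figures are conventionally annotated.

**Technical replicates** (each sample is run at least in duplicate) are
pooled by arithmetic mean into one biological row; the replicate-level
table is kept as an attribute for audit.

**Coupling metrics.** From a coupling protocol,
`omy_inhibition_pct = 100 (1 - J_{OMY}/J_{PMDGS})` estimates the share of
maximal respiration linked to ATP synthesis (higher = more coupled),
`residual_pct = 100\, J_{AMA\_ROT}/J_{PMDGS}` the non-mitochondrial
residual, and `cc_response_pct` the relative gain upon cytochrome c — an
outer-membrane integrity check, near zero for intact preparations.

# The three normalization schemes

Wet-weight flux confounds three quantities: tissue density/hydration,
total cellular protein per mg, and the mitochondrial fraction of that
protein. The scheme chain disentangles them:

* **wet_weight** — the raw per-mg scale of the state table.
* **total_protein** — divides by the group mean µg protein per mg wet
  weight from a Bradford table (`proteinFactor()`): removes
  density/hydration differences.
* **mef** — further divides by the group MEF,
  $\mathrm{MEF}_s = \sum_{\mathrm{mito}} a_{is} \big/ \sum_{\mathrm{all}} a_{is}$,
  computed per sample from a MitoCarta-style-annotated label-free proteome
  and averaged within group (`computeMEF()` returns both). The result is
  flux per unit mitochondrial protein — the intrinsic scale.

Group factors (not per-sample factors) are the default because flux and
proteome samples need not be the same animals; per-sample MEF values are
exposed for cohorts where they are. The algebraic identity
`mef-normalized = total-protein-normalized / MEF` holds exactly, and since
each scheme is a positive per-group scalar, within-group sample ranking is
invariant — both are tested properties.

The same chain applies to H2O2 emission rates: `calibrateH2O2()` fits the
linear Amplex-Red-style standard curve (fluorescence versus known
concentration, OLS), converts each kinetic trace to concentration, takes
the slope, and emits a flux-like table (`analyte = "H2O2"`) that
`applyNormalization()` treats identically. No numeric benchmark is set on
ROS directionality across schemes: it depends on group factors that are
cohort-specific.

# Omics operations

* `detectFeatures()` calls a feature "detected in a group" when observed in
  ≥ `minSamples` (default 3) of its samples — robust to single-sample
  artifacts — and partitions features into shared / group-exclusive sets.
* `differentialAbundance()` is a deliberately simple stand-in for
  dedicated DE machinery (which is off-the-shelf and accepted as external
  input): per shared feature, log2 fold change as a difference of group
  means of `log2(x + pseudocount)`, Welch t, BH adjustment, significance
  at `padj < 0.1`. Pseudocounts default to 1.0 for protein intensities and
  0.5 for TPM (scale-dependent; configurable). Zero-variance-in-both
  features get `p = 1` with a flag, never `NaN`. The row-wise Welch
  formulas are vectorized; equality with `stats::t.test` per feature is
  asserted in the tests.
* `complexSummaries()` sums detected subunit abundance per respiratory
  complex relative to either the mitochondrial or the total proteome sum;
  the two denominators differ exactly by the sample MEF (tested identity).
* `integrateLayers()` matches DE tables by case-folded gene symbol,
  reports the Pearson correlation of log2 fold changes, and the jointly
  significant co-directional overlap sets. Duplicate symbols collapse to
  one row by maximum `mean_abundance` when the tables carry that column;
  DE tables in the minimal format carry none, so the fallback is minimum
  `padj` (ties: larger |log2fc|), with collapsed symbols reported.

# Cell-type-weighted OXPHOS scoring

Bulk-tissue OXPHOS transcript levels mix cell types with very different
mitochondrial programs. To attribute the bulk signal, two percent-scale
quantities are combined. From a single-cell reference atlas:
$\%Expression_{CT}(t, c)$ = the mean, over subunit genes $g$ of complex
$c$, of the percentage of cells of type $t$ expressing $g$, multiplied by
the cell-type proportion of $t$ in the atlas (the weighting sits here, at
the expression step). From tissue immunofluorescence:
$\%Immunopositive_{CT}$ = the percent of tissue area positive for the cell
type's marker. Then per group, cell type, and complex

$$ \mathrm{OXPHOS\ mRNA\ Index} = \%Expression_{CT} \times \%Immunopositive_{CT}, \qquad \mathrm{Total\ Score} = \sum_{c \in \{CI..CV\}} \mathrm{Index}_c . $$

The index is the literal product of two percent-scale quantities (units
% × %): it ranks cell-type contributions and is never rescaled. Atlas cell
types are harmonized to the coarser immunofluorescence panel by an
editable map (`defaultCellTypeMap()`): cancer + normal epithelial →
epithelial, CAFs + PVL → mesenchymal, B cells unmapped. Because atlas
proportions weight each type before pooling, harmonization *sums* the
weighted expression values — the natural pooled estimate. When genes are
missing in some cell types the per-complex mean is taken over the genes
present; unmapped genes are dropped with a log message. Both choices are
declared, not inferred from any upstream convention.

Tested invariants: scaling all `pct_expressing` by $k$ scales every index
and score by $k$; with equal expression across cell types, score ranking
equals immunopositive-area ranking.

# Statistics

Welch's t is the default two-sample test (tumor-vs-benign variances are
rarely equal); the pooled-variance Student variant sits behind
`pooled = TRUE` for comparability with legends that report Student's t.
Cohen's d uses the n−1-weighted pooled SD. Post hoc power of the
two-sided two-sample t-test is computed from the noncentral t
distribution with `df = 2n − 2` and noncentrality `d·√(n/2)`, *including
both rejection tails* — so `power(d = 0) = α` exactly. (Base R's
`power.t.test` drops the far tail; the two agree to ~1e−5 at the effect
sizes of interest and the construction is additionally validated against
Monte-Carlo rejection rates.) Unequal group sizes use the harmonic-mean
effective n, flagged by the length-2 argument form. BH adjustment
delegates to `stats::p.adjust` and is property-tested against a
brute-force transcription of the step-up definition.

# The synthetic-data generator

`generatorConfig()` fixes the cohort the pipeline is validated on. The
defaults emulate a benign-mammary-tissue versus HER2-driven-tumor design:

| parameter | benign | tumor | rationale |
|---|---|---|---|
| `n_samples` (respirometry) | 14 | 14 | matches the tissue design scale at which >99% power is reported |
| `true_jo2` PMDGS (pmol/s/mg) | 5 | 35 | 7-fold wet-weight ratio, inside the observed 4.9–9.9× range |
| `coupling_fraction` | 0.55 | 0.80 | oligomycin inhibits benign ~55%, tumor ~80% |
| `residual_fraction` | 0.02 | 0.02 | antimycin A + rotenone fully inhibit |
| `content_scale` | 1.0 | 0.5 | tumor mitochondrial proteome downregulated to half |
| `amount` (mg/chamber) | 18 | 3.5 | typical loadings (15–20 mg benign, 2–5 mg tumor) |
| `protein_ug_per_mg` | 80 | 100 | tumors are denser in protein |
| `noise_sd` (µM) | 0.2 | 0.2 | realistic trace noise for a 2 ml chamber |
| `bio_cv` | 0.30 | 0.30 | between-sample CV in the reported 23–46% band |

Traces start at 180 µM O2 in a 2 ml chamber, sampled every 2 s with 300 s
state segments; proteomes use 5 samples/group, transcriptomes 6, with 2000
features of which 15% are mitochondrial (the 84 built-in OXPHOS subunit
genes plus filler), log-normal abundances (log2 sd 0.5), and
abundance-independent Bernoulli dropout (default rate 0.1) — the simplest
model that reproduces unique/shared detection sets. Each biological sample
yields two technical-replicate traces sharing one multiplicative
between-sample factor, so replicate pooling and biological variability are
separable. All simulators are byte-deterministic under a fixed seed.

`contentScalingConfig()` builds the diagnostic scenario at the heart of
the normalization logic: two groups with *equal intrinsic flux per unit
mitochondrial protein* but content scaled by `c`. Since MEF is a ratio,
scaling mito abundance by `c` moves the group MEF from `m` to
`cm/(cm + 1 − m)`; the wet-weight ladder is scaled by exactly that factor
so that MEF normalization recovers equality. With `c = 0.5` and `m = 0.15`
the wet-weight fluxes differ ~1.9-fold while MEF-normalized fluxes agree —
the signature that separates a content change from an intrinsic one.
Conversely, under the default presets (content halved *and* intrinsic flux
elevated) the tumor/benign ratio survives every normalization, which is
the qualitative headline the pipeline is designed to resolve.

**What the generator does not emulate:** instrument background-flux drift
and re-oxygenation events; abundance-dependent (censoring-type) detection
dropout, unless the optional flag is raised; correlated noise across
features; batch structure; and any enrichment-database structure. Passing
tests on synthetic cohorts therefore demonstrate estimator correctness and
the normalization algebra, not robustness to those real-data pathologies.

# Numerical choices and degenerate inputs

* OLS windows need ≥ 3 points; fewer is an error (`estimateJO2`) or a
  missing-state flag (`segmentStates`).
* `frac_mito` of exactly 0 or 1 yields a proteome flagged `degenerate` in
  metadata (with a warning) rather than an error, so edge behavior is
  inspectable.
* TPM columns are renormalized to sum to 1e6 and validated to 1e−6
  relative tolerance.
* MEF = 0 groups cannot normalize (error); zero-total-abundance samples
  are an error in `computeMEF`.
* Problem sizes in the shipped tests and acceptance script — 30-seed
  Monte-Carlo for the content contrast, 20 samples/group for coupling
  recovery, 200 null replicates of a 1000-feature proteome for FDR — were
  chosen so each check's Monte-Carlo error is well inside its assertion
  band.

# Known limitations

* The differential-abundance stand-in is a per-feature Welch t on log2
  intensities: no shrinkage, no count model. Real cohorts should supply DE
  tables from dedicated tools; the integration layer accepts them
  directly.
* Group-average normalization factors propagate no uncertainty into the
  normalized fluxes; comparisons across schemes are point estimates.
* The OXPHOS mRNA Index assumes the atlas percent-expression of a cell
  type transfers across cohorts and species context; it ranks
  contributions rather than estimating absolute transcript shares.
* Trace segmentation assumes injections are annotated; event detection
  from the O2 signal itself is out of scope.
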