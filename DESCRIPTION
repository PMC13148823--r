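Package: mitoflux
Title: Bioenergetic Analysis of Tissue Respirometry with Mitochondrial-Content Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing high-resolution respirometry of permeabilized
    tissue alongside matched proteomic and transcriptomic profiling. Extracts
    steady-state oxygen fluxes from substrate-uncoupler-inhibitor titration
    (SUIT) traces, computes OXPHOS coupling metrics, and normalizes fluxes to
    wet weight, total protein, or a mitochondrial enrichment factor (MEF)
    derived from a MitoCarta-style annotated proteome. Includes
    detection-set logic, differential abundance, per-complex OXPHOS subunit
    summaries, transcriptome-proteome fold-change integration, a
    cell-type-weighted OXPHOS mRNA index/score, two-sample power and effect
    size statistics, and a synthetic-data generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
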