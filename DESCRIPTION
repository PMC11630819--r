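Package: vomeroseq
Title: Receptor Expression Logic in Vomeronasal Single-Cell Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse chemosensory receptor expression logic in
    single-cell RNA-seq count matrices of the vomeronasal organ (VNO):
    per-class receptor expression summaries and rank-probability power-law
    fits, presence-threshold based receptor co-expression calling with
    one-sided Fisher exact tests and Benjamini-Hochberg correction,
    Shannon diversity of receptor expression per cell, genomic
    co-localization of co-expressed receptor pairs, receptor to
    transcription-factor and axon-guidance association tables with
    per-receptor Jaccard grids, and marginal/intermediate/main spatial
    zone assignment with cell-type enrichment tests. A synthetic-data
    generator with planted ground truth (power-law receptor choice,
    co-expressed pairs, receptor-linked TF/AG programs, ambient and
    capture noise, zone enrichment) supports recovery testing of every
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    Biostrings,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cli.R'
    'code.R'
    'coexpression.R'
    'io-read.R'
    'io-write.R'
    'quantify.R'
    'synthetic-generate.R'
    'synthetic-truth.R'
    'utils.R'
    'vomeroseq-package.R'
    'zones.R'
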