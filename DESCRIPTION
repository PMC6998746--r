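Package: panelCNV
Title: Read-Depth CNV Flagging for Targeted Hereditary-Cancer Capture Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Exon-level copy number variant (CNV) flagging from hybrid-capture
    read-depth data on clinical gene panels. Capture targets are partitioned
    into ~200 bp bins and joined into hierarchical target groups (single bin,
    exon, multi-exon window, whole gene); per-specimen depth is normalized in
    three stages (relative depth, principal-component denoising, median
    scaling) and scored with robust Z and noise-adjusted Z statistics against
    per-group dispersions and cutoffs learned from a training cohort. Includes
    a negative-binomial coverage simulator with CNV spike-in truth sets, QC,
    model serialization, call merging with TSV/VCF export, and trial-level
    validation metrics (sensitivity, specificity, intra/inter-assay precision).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cli.R'
    'coverage.R'
    'metrics.R'
    'normalize.R'
    'panel.R'
    'score.R'
    'simulate.R'
    'train.R'
    'utils.R'
    'validation.R'
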