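Package: markstates
Title: Integrating Histone-Mark and Transcription-Factor Occupancy with
    Gene Activity in Differentiating Trophoblast Stem Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for epigenome-transcriptome integration in
    time-course ChIP-seq/RNA-seq studies of trophoblast stem cell
    differentiation. Calls transcriptionally active and silent genes by the
    zFPKM transform, classifies differentially expressed genes by fold
    change, derives a regulatory-element taxonomy (promoters, putative
    enhancers, gene bodies), builds gene-level mark-occupancy tables across
    timepoints, classifies combinatorial occupancy states and gain/loss
    dynamics, assigns co-factor complex categories at promoters, computes
    within-chromosome shuffle nulls for peak-set overlap, and profiles
    scaled-region metagene signal. Includes a synthetic-study generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
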