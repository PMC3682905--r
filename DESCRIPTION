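Package: ervpipe
Title: Retroelement Expression, ChIP Flank Profiling and LTR-Driven
    Transcript Analysis
Version: 0.9.0
Authors@R:
    person("ervpipe", "maintainers", email = "ervpipe@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for endogenous retrovirus (ERV) silencing
    studies in mouse embryonic stem cells: RPKM quantification of repeat
    families and individual full-length proviruses with a Poisson-model
    pairwise Z-score, ChIP-seq coverage metaprofiles and heatmaps in the
    regions flanking intact LTR-internal-LTR elements, detection of
    chimeric LTR-gene transcripts from discordant paired-end alignments,
    and classification of two-cell-embryo-specific genes with MT2-LTR
    proximity enrichment. Includes a deterministic synthetic-data
    generator (toy genome, SAM alignments, stage-expression tables) with
    ground-truth output for recovery testing, and a pipeline driver with
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
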