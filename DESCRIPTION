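Package: nanorevise
Title: Post-Basecalling Error Correction for Nanopore Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Revises basecalled nanopore reads using the raw current signal.
    Basecaller events are re-segmented to one event per called base, labeled
    from reference alignments (error-type and true-base labels), and windows of
    signal plus event features are fed to two recurrent-convolutional networks
    trained with a softmax cross-entropy plus center loss objective. Their
    per-event predictions are merged by fixed rules into a corrected read.
    Includes alignment-based error-rate metrics (optionally stratified by
    methylation type), a fully synthetic squiggle/event/alignment generator
    with known ground truth, and a small command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
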