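Package: PileupScrub
Title: Scrubbing Low-Quality Segments from Long Noisy Reads with
    Overlap Pileup Images and a Convolutional Regressor
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects and removes ("scrubs") low-quality internal segments of
    long noisy sequencing reads such as Oxford Nanopore reads. Reads are
    sketched with (w,k)-minimizers, overlapped all-vs-all by co-linear shared
    minimizers, and each read's overlap pile is encoded as an RGB pileup
    image whose columns are reference-read minimizers. Fixed-width image
    segments are regressed to per-segment percent identity with a small
    convolutional neural network trained on reads with known identity; reads
    are then split at below-threshold segments and written back to FASTQ.
    Includes a seeded long-read simulator with a ground-truth error track for
    end-to-end training and evaluation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    data.table,
    jsonlite,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
biocViews: Sequencing, QualityControl, Preprocessing, Alignment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
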