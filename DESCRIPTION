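Package: spikenorm
Title: Spike-In Normalization and Reproducibility Analytics for ChIP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements four ChIP-seq normalization strategies (counts per
    million, equal-read, spike-in, and input-adjusted spike-in) as scaling
    factors for seeded fractional read downsampling, together with the
    downstream analytics needed to compare them: dual-genome read
    classification and counting, fixed-width windowed coverage tracks, a
    minimal Poisson peak caller, multi-replicate overlap partitions and
    consensus peaks, and peak-centered signal matrices. A dual-genome
    simulator with ground truth generates synthetic spike-in ChIP-seq
    experiments so every stage can be exercised and calibrated without
    external data. All user-facing functions take and return data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicAlignments,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
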