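Package: dubseqr
Title: Analysis of Dual-Barcoded Shotgun Expression (Dub-seq) Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes dual-barcoded shotgun expression (Dub-seq)
    libraries from sequencing reads and quantifies pooled fitness. Extracts
    random DNA barcodes from BPseq, BAGseq and BarSeq reads with
    flanking-sequence anchors and quality gates, filters one-off and
    chimeric-PCR barcode artifacts, maps barcode-adjacent genomic tails to a
    reference genome with a seed-and-extend aligner, joins barcode pairs with
    genomic junctions into a fragment reference set, computes median-centered
    log2 fragment fitness scores from barcode counts, deconvolves fragment
    scores into per-gene scores by non-negative least squares (positive and
    sign-flipped passes), scores adjacent gene pairs for epistatic effects,
    and calls reliable and high-confidence effects with magnitude,
    consistency and Poisson-noise filters plus a shuffle-based false
    discovery rate estimate. A synthetic-data generator provides truth
    tables for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
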