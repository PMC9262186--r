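Package: termscan
Title: Structure-Aware Deep Learning for Intrinsic Transcription Terminator Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects intrinsic (rho-independent) transcription terminators in
    bacterial genomes with convolutional neural network classifiers trained on
    one-hot encoded sequences or base-pairing potential matrices. Implements
    inverse-folding based pre-training, in which structure-equivalent RNA
    sequences are generated for a set of target secondary structures and used
    to initialise model weights before fine-tuning on curated terminator data.
    Includes a seeded synthetic-data generator for annotated hairpin
    terminators, tRNA-like cloverleaves and genomes with implanted elements;
    a weighted maximum-pairing folder with inverse-folding search (internal
    stochastic search or an external RNAinverse backend); an in-silico
    mutagenesis framework quantifying relative activation impact of sequence
    sections and of stem base pairing; and a transcriptome-wide sliding-window
    scan with distance-threshold precision-recall evaluation against mapped
    termination sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
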