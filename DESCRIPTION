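Package: xylosig
Title: Histone Modification Signal Quantification and Transcript
    Abundance Modelling Around Transcription Start Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for activating (H3K4me3-like) and
    repressive (H3K27me3-like) histone-modification ChIP-seq signal and
    transcript abundance. Quantifies nett (treatment minus input) coverage
    in forty 100-bp bins anchored at the transcription start site, calls
    peak occupancy and bivalent chromatin states, predicts Yeo-Johnson
    transformed FPKM by train/test multiple linear regression with partial
    eta-squared variance partitioning, clusters term representation
    across peak-length classes with a weighted peak-length score and a
    binomial inflation test, and measures Shannon-entropy tissue
    specificity. Includes a synthetic-data generator that plants known
    signal-expression relationships so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite
Config/testthat/edition: 3
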