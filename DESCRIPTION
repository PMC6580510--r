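Package: coldchrom
Title: Cold-Stress Chromatin Accessibility and Bivalent Histone Mark Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cold-stress chromatin dynamics: DNase I
    hypersensitive site (DHS) identification from cut-site tracks by Gaussian
    kernel density estimation with Monte-Carlo empirical FDR control,
    replicate-consensus and condition-specific DHS sets, summit-based genomic
    feature assignment, normalized 100-bin metagene profiles of DNase and ChIP
    signal, input-normalized ChIP quantification, and dual-order sequential
    ChIP (re-ChIP) calling of bivalent H3K4me3-H3K27me3 genes. Includes a
    synthetic-data generator that emulates the structure of a two-replicate,
    three-sample (room-temperature tuber, cold tuber, leaf) potato study so
    every stage is testable without external downloads, plus the proportion
    z-test, Wilcoxon rank-sum, and windowed-correlation reporting used
    throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    BiocGenerics,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
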