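Package: mirquant
Title: Small RNA-Seq Quantification and Negative Binomial Differential
    Expression for QIAseq-Style miRNA Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully tested implementation of a miRNA-seq
    processing and statistics pipeline for QIAseq-style libraries: adapter
    location and UMI extraction, BWA-style 3' quality trimming, length
    filtering and UMI-based deduplication; two-step quantification by exact
    sequence assignment against mature miRNA references ("precounting") with
    an alignment-based fallback over genomic miRNA features; median-of-ratios
    normalisation, per-feature negative binomial dispersion estimation, Wald
    tests with Benjamini-Hochberg correction and UP/DOWN fold-change
    classification; hypergeometric pathway over-representation analysis; and
    a synthetic-data generator producing references, UMI-tagged FASTQ
    libraries and two-condition count matrices with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
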