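Package: bivalink
Title: Bivalent Chromatin Domain Calling Across Developmental Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies bivalent (H3K4me3 + H3K27me3) promoters from binned
    FPKM coverage tracks across developmental stages. Implements saturation
    normalization of promoter signal (median of the top-N promoters as the
    per-stage anchor), calibration of a single unified bivalency threshold
    against a peak-derived reference region count, per-stage bivalent gene
    calling with the max-over-TSS rule, and classification of bivalency
    transitions between stages (stage-specific versus shared sets, with
    expression summaries). Ships a synthetic-data generator with planted
    truth so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
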