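Package: mpravar
Title: Variant Effect Analysis for Native-Promoter Massively Parallel
    Reporter Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of massively parallel reporter assay
    (MPRA) experiments that couple cis-regulatory elements to their
    native promoter: barcode-variant association from long reads,
    UMI-deduplicated DNA/RNA barcode counting, per-variant log2
    fold-change statistics with Benjamini-Hochberg correction,
    position-weight-matrix motif gain/loss annotation, sliding-window
    Poisson hotspot detection, and haplotype additivity assessment.
    Includes a seeded synthetic-data generator emulating the assay
    design so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
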