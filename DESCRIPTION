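Package: dielshift
Title: Comparative Diel Rhythmicity and Network Rewiring Analysis for
    Two-Condition Expression Timecourses
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects 24-hour rhythmic gene expression in parallel two-condition
    diel timecourses (for example well-watered C3 versus drought-induced
    CAM-cycling plants) with a nonparametric Kendall-tau template test using an
    exact dynamic-programming null, classifies per-gene rhythm changes between
    conditions (gain, loss, amplitude and circular phase shifts), tests
    phase-specific and promoter cis-element (IUPAC motif and exhaustive
    3-8-mer) enrichment, and compares per-condition signed co-expression
    module partitions and mutual-information interaction networks to identify
    condition-specific activators and suppressors of target genes. Includes a
    synthetic-data generator that emulates the two-condition diel study design
    with known ground truth, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    optparse,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
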