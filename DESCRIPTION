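Package: scafrag
Title: Fragment-Level Processing and Allele-Aware Analysis of
    Tag-Multiplexed Single-Cell ATAC-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for processing tag-multiplexed single-cell ATAC-seq data
    at the fragment level: cell-barcode and transposon-tag (META tag)
    demultiplexing with mismatch tolerance, mosaic-end adapter trimming,
    Tn5-centered fragment construction, tag-aware PCR-duplicate removal and
    cross-cell decontamination, per-cell quality metrics (library complexity
    via the Lander-Waterman model, TSS enrichment, fraction of fragments in
    peaks, species-mixing classification, DHS saturation), hypergeometric
    peak-pair coaccessibility scoring with distance profiles and
    precision-recall evaluation, allele-specific accessibility statistics
    with X-inactivation assignment, UMI filtering and collapsing for a
    paired RNA modality, and a seeded synthetic-data generator with
    ground-truth ledgers for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
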