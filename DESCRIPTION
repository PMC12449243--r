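Package: ontcells
Title: Barcode Demultiplexing, UMI Deduplication and Quantification for
    Long-Read Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for the bespoke secondary-analysis stages of Oxford
    Nanopore single-cell RNA-seq: quality/length filtering and 10X read
    structure parsing (adapter, 16 nt cell barcode, UMI, poly-T) from noisy
    long reads, abundance-ranked whitelist construction with knee detection,
    Bayesian barcode correction over Hamming-neighbourhood candidates,
    SAM/BAM tagging with the CR/CB/UR/CY/UY tag set, per-cell UMI
    deduplication by the directional network method, sparse barcode-by-feature
    count matrices in MatrixMarket layout, and multi-stage read-count
    tracking. Includes a deterministic synthetic-read simulator (toy
    reference, ONT-like errors, truth tables, perfect-placement SAM) so the
    whole pipeline is verifiable at desk scale without an aligner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Matrix,
    rtracklayer,
    Rsamtools,
    methods,
    stats,
    utils,
    tools
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
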