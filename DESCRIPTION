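Package: sRNAstress
Title: Small RNA Profiling of Plant Water-Stress Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested re-implementation of a small RNA sequencing analysis
    for maize and teosinte under submergence, drought, and alternated
    water stress. Covers adapter trimming and read cleaning, unique-tag
    collapsing, exact genome mapping with non-coding RNA classification,
    mismatch- and offset-tolerant annotation of mature miRNAs (isomiR
    positional variants), tags-per-million normalization, threshold-based
    differential expression with a raw-count floor, collapsing of
    positional variants into representative miRNA groups with recalculated
    fold changes, directional cross-condition overlap and attenuation
    analysis, organelle-derived read hotspot detection, and the bench-side
    formulas (relative water content, submergence tolerance coefficient,
    stem-loop qPCR delta-delta-Ct). A synthetic-data module generates toy
    references and per-condition FASTQ libraries with known ground truth
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
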