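Package: scecc
Title: Single-Cell Extrachromosomal Circular DNA Detection and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for single-cell circle-enrichment sequencing of
    extrachromosomal circular DNA (eccDNA). Detects circle-producing
    regions (CPRs) from per-cell alignments via coverage enrichment,
    calls chimeric junctions from split reads, classifies CPRs across a
    cell population by frequency of occurrence and a mitochondria-
    normalized uniformity score, and provides downstream landscape
    statistics (coverage autocorrelation, GC comparison, meta-gene
    profiles, feature overlap, co-occurrence, expression correlation,
    copy-number-stratified density, daughter-cell distances) and latent
    Dirichlet allocation topic modeling of circle-read bin matrices.
    Includes an alignment-level simulator of circular-DNA sequencing
    data with planted circles, a mitochondrial surrogate and circular/
    linear spike-ins, used as the validation test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    data.table,
    jsonlite,
    optparse,
    rtracklayer,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
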