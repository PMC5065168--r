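Package: karyoshatter
Title: Copy-Number Aberration Calling, Chromothripsis Detection and
    Cytogenetic Concordance for Myeloid Disorder Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Segments array-CGH log2-ratio profiles into piecewise-constant
    copy-number profiles by exact penalized least-squares changepoint
    detection, calls copy-number gains and losses with three-state copy
    assignment, filters germline copy-number variants by reciprocal overlap,
    and detects chromothripsis as oscillating copy-number states on a single
    chromosome. Integrates targeted-sequencing mutation tables with deletion
    calls (variant-allele-frequency zygosity, biallelic status, minimal
    deleted regions), parses simplified ISCN karyotypes and measures
    concordance between conventional cytogenetics and array results. A
    synthetic-cohort generator with implanted ground truth makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
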