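Package: switchsig
Title: Context-Specific Apoptosis Signatures from TGFB1 and MEK Inhibitor Co-Treatment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis pipeline for melanoma phenotype-switching studies
    that combine bulk RNA-seq treatment series (DMSO, TGFB1, MEK inhibitor, and the
    double treatment), SMAD4 CUT&RUN binding intervals, curated gene-set universes,
    and MTT dose-response assays. Provides negative-binomial differential expression
    with median-of-ratios normalisation and Wald tests, row z-scored hierarchical
    clustering with fixed-k dendrogram cuts, weighted Kolmogorov-Smirnov gene set
    enrichment with permutation significance, treatment-specific signature derivation
    and expression-bin-matched module scoring, replicate-reproducible consensus peaks,
    GREAT-style regulatory-domain peak-to-gene association, multi-set Venn partitioning
    and assembly of a context-specific apoptosis signature, position-weight-matrix
    motif enrichment, and four-parameter logistic IC50 fitting with flat-curve
    handling and sensitivity classification. A seeded synthetic-data generator with
    known ground truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
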