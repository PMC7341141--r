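Package: qtgrank
Title: Prioritizing Candidate Causal Genes in Plant QTL Intervals
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ranks candidate causal genes inside plant quantitative trait
    locus (QTL) intervals with a negative-resampling random-forest ensemble.
    Training sets are assembled from known causal genes and, for species with
    few or no cloned causal genes, from orthologs of causal genes in other
    species.  Per-gene features are built from effect-annotated variant calls,
    polymorphism counts in conserved non-coding elements, gene
    presence/absence variation across accessions, GO-slim function flags and
    paralog copy number.  Includes cross-validation, leave-one-out feature
    importance, recall-at-top-k% external validation with exact-test model
    comparisons, and a synthetic-species simulator so the whole pipeline can
    be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
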