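Package: GSRegularity
Title: Gene Set Regularity Scoring and Functionome Analysis for Expression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Quantifies, per gene set and sample, how far the within-set
    gene-expression ordering departs from a control-derived baseline ordering
    template (a rank-conservation score in [0,1], a modification of
    differential rank conservation), and provides the downstream functionome
    toolkit: Mann-Whitney/Benjamini-Hochberg deregulation ranking, top-k set
    analysis, progressive-ranking selection across disease stages,
    linear-SVM cross-validated classification of functionome patterns,
    hierarchical clustering of group means, k-nearest-neighbour mutual
    information network inference with data-processing-inequality pruning
    and GML export, cross-platform integration by the cumulative-proportion
    transform, moderated-t differential expression, and a synthetic
    multi-stage cohort generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    limma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
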