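Package: morphrisk
Title: Genetic Risk Effects on Cortical Morphology via Classification and
    Morphological Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for detecting effects of Alzheimer's-disease risk
    genotypes (APOE e4 and MAPT rs242557 A) on regional cortical morphology
    in young adults. Provides a synthetic-cohort generator with planted
    genotype effects, curvature-derived metric formulas and readers for
    FreeSurfer-style regional statistics, leakage-guarded covariate-adjusted
    feature screening inside cross-validation, stratified 5-fold linear
    support-vector-machine genotype classification with permutation
    significance and hyperplane weight-map summaries, a growing hierarchical
    self-organizing map (GHSOM) that clusters cortical regions into
    morphological profiles, per-participant intra-cluster distances, and
    gene-gene interaction general linear models with false-discovery-rate
    and Bonferroni corrections.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
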