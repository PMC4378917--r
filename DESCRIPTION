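Package: phenoforest
Title: Multidimensional Clinical Phenotyping with Unsupervised Random Forests
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised clinical phenotyping of mixed-type patient feature
    tables, built around a bespoke classification Random Forest (bootstrap
    CART trees, out-of-bag error, permutation variable importance, and the
    pairwise proximity matrix), Partitioning Around Medoids (PAM) on the
    1-proximity dissimilarity, and classical multidimensional scaling.  A
    two-stage pipeline clusters subjects on all variables, ranks variables by
    permutation importance, and re-clusters on the most important ones.
    Includes class-versus-rest trait enrichment (two-sided Fisher exact tests
    with Benjamini-Hochberg correction), longitudinal phenotype stability
    analysis across paired cohorts, and a synthetic cystic-fibrosis-like
    cohort generator with known latent classes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    randomForest,
    cluster,
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
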