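Package: metamwas
Title: Metagenome-Wide Association Analysis with Permutation-Calibrated
    Significance Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A case-control metagenome-wide association study (MWAS) toolkit
    for shotgun-metagenomics cohorts: multi-level taxonomic relative-abundance
    construction from per-genome read counts, detection and abundance feature
    filters, Box-Cox and rank-based inverse normal transformations,
    covariate-adjusted logistic association scans, phenotype-permutation
    estimation of empirical metagenome-wide significance thresholds and
    rank-wise empirical false discovery rates via the Harrell-Davis quantile
    estimator, effect-size-ranked gene-set enrichment, MWAS-GWAS pathway
    overlap testing, and alpha/beta-diversity comparisons. Includes a
    synthetic-cohort generator so every stage runs end-to-end without access
    to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
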