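Package: missnp
Title: Misclassified-Sample Re-Modeling for GWAS Case-Control Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for building L1-regularized logistic
    classifiers from case-control GWAS genotypes, with a feedback step that
    re-models misclassified samples and merges the resulting markers back
    into the main model. Includes PLINK text/binary input and output, a
    subject- and SNP-level quality-control cascade (ancestry PCA, call
    rate, monomorphism, Hardy-Weinberg filtering), pedigree-based kinship
    estimation with a kinship-corrected chi-square association test for
    family data, k-nearest-neighbour genotype imputation, cross-validated
    LASSO model building and evaluation, and a synthetic-cohort generator
    that plants a hidden genetic sub-class for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
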