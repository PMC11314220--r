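Package: tocopls
Title: Candidate-Gene Association Analysis of Adipose Tissue
    Alpha-Tocopherol via PLS Regression with VIP Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for candidate-gene association analysis of subcutaneous
    adipose tissue alpha-tocopherol concentration in small cohorts: genotype
    quality control (call rate, Hardy-Weinberg chi-square, tag-SNP selection
    by dosage r-squared, perfect-correlation de-duplication), technical
    replicate processing with Grubbs outlier screening, coefficient-of-
    variation inference (Forkman's test), univariate SNP screening under
    additive and dominant codings, a from-scratch NIPALS PLS1 engine with
    variable importance in projection (VIP), cross-validated Q2, CV-ANOVA and
    permutation validation, VIP-threshold model selection, and an affine
    genetic score for predicting adipose alpha-tocopherol concentration from
    genotypes. Includes a seeded synthetic cohort generator emulating the
    study design (42 participants, replicate adipose measurements, linear
    genetic architecture) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
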