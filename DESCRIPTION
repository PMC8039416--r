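Package: col4eval
Title: Evaluation of Computational Pathogenicity Predictions for Type IV
    Collagen Missense Variants
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing in silico pathogenicity predictions of
    COL4A3, COL4A4 and COL4A5 missense variants. Implements
    population-matched minor-allele-frequency rarity filtering, a
    12-program consensus classifier (a variant is predicted pathogenic
    when at least 10 of 12 predictors vote deleterious at their
    recommended cutoffs), concordance analysis against clinically
    labelled disease-database strata, ROC-based cutoff recalibration
    via the Youden index, cross-predictor Spearman correlation, and
    analysis of split-luciferase secretory-defect assays with a
    wild-type-referenced band rule. Ships a self-verifying
    synthetic-data generator that reproduces the stratum count
    configurations the methods were characterized on.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: VariantAnnotation, Classification, FunctionalPrediction,
    Software
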