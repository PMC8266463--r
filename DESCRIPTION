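Package: statureprs
Title: Polygenic and Parental Predictors of Adult Stature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for comparing polygenic risk
    scores against mid-parental height as predictors of adult height and as
    screening tools for future adult short stature. Includes a trio cohort
    simulator with Mendelian transmission, assortative mating and shared
    family environment; a desk-scale polygenic score construction pipeline
    (marginal association, inverse-variance meta-analysis, LD clumping with
    p-value thresholding, and LASSO); PGS-Catalog-style scoring file support
    with allele harmonization; the classical and adapted mid-parental height
    formulas and the Khamis-Roche adult height predictor with a pluggable
    genetic component; and a full evaluation suite (adjusted R-squared, RMSE,
    AUROC, AUPRC, odds ratio per SD, nested likelihood-ratio tests, bootstrap
    confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    pROC
Config/testthat/edition: 3
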