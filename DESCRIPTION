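Package: fuwas
Title: Functional-Unit-Wide Association Studies with Penalized Regression
    and Stability Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Groups genetic variants by their predicted regulatory impact on
    functional units (a chromatin feature in a cell line, optionally under a
    treatment), filters variants by empirical e-values against a background of
    random variants, and tests each functional unit's variant set jointly for
    trait association using L1-penalized regression with stability selection
    under per-family error-rate control. Includes a univariate GWAS baseline
    with inverse-variance fixed-effects meta-analysis, train/test AUC
    comparison of set-based versus single-variant predictors, dosage-based LD
    pruning and proxy search, cis-window expression and methylation QTL scans
    with FDR control, permutation enrichment of selected variants in
    annotation sets, a dummy-node graph integrating variant, functional-unit,
    and QTL associations, and a synthetic-data generator with known ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
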