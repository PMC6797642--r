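Package: blocksca
Title: Regularized Simultaneous Component Analysis of Multiblock Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint decomposition of several data blocks sharing the same
    samples into common and distinctive components. Implements simultaneous
    component analysis (SCA) with Lasso and Group Lasso penalties solved by
    closed-form conditional updates under an orthonormal score matrix,
    together with a model-selection toolbox: variance-accounted-for (VAF)
    screening, DISCO rotation search over candidate common/distinctive
    structures, PCA-GCA canonical-correlation screening, maximal-penalty
    computation, and cell-wise K-fold cross-validation with the
    one-standard-error rule. Includes OLS re-estimation to undo
    penalty-induced shrinkage and a synthetic multiblock data generator
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
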