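Package: rimmune
Title: Radiomic Prediction of the Tumor Immune Microenvironment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to relate quantitative CT imaging phenotypes of lung tumors
    to their immune microenvironment. Implements a 239-feature radiomic
    catalog (histogram, shape, gray-level texture matrices, Laplacian-of-
    Gaussian filter bank, fractal and tumor-margin sigmoid features,
    including peritumoral inner/outer/delta region statistics), rank-based
    single-sample gene-set enrichment scoring of immune cell signatures with
    PCA and cohort-mean dichotomization, and multi-classifier prediction of
    helper and cytotoxic T-cell status evaluated by the 0.632 bootstrap.
    Includes a synthetic phantom and expression generator with planted
    image-immune coupling so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    glmnet,
    rpart,
    ranger,
    minpack.lm,
    RNifti,
    yaml,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    MASS,
    e1071,
    pROC,
    caret,
    fgsea,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
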