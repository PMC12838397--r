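Package: pathqc
Title: Predicting Biospecimen Quality Metrics from H&E Histology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for predicting specimen-quality metrics (RNA
    Integrity Number and histological autolysis score) from hematoxylin and
    eosin stained tissue images. Provides Sobel-gradient tissue masking,
    Macenko stain normalization, fixed-grid patch tiling, pluggable patch
    encoders, multi-statistic slide-level embedding aggregation, tissue-specific
    L1-penalized regression with cross-validated penalty selection, a two-stage
    pan-tissue framework (tissue classification followed by confidence-gated
    routing to tissue-specific quality models), and diagnostic analyses:
    confounder variance decomposition, quality-metric correlation, feature
    importance and sharing, fold-stability coefficients of variation, and
    preservation-percentile robustness curves. A synthetic-data module
    generates stain-mixed tissue tiles and slide-embedding datasets with
    planted signal so every stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    Matrix,
    EBImage,
    png,
    pROC,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
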