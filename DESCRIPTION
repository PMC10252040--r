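Package: sweatvoc
Title: Sweat Volatolomics Discrimination from GCxGC-MS Descriptor Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for vectorized two-dimensional gas
    chromatography-mass spectrometry (GCxGC-MS) sweat volatolomics data.
    Provides delimited-text readers and validation for descriptor peak-area
    tables, a zero-inflated log-normal cohort simulator with batch and
    planted pre/post-surgery effects, log/standardize preprocessing with
    Mann-Whitney descriptor ranking and PCA, SMOTE class rebalancing,
    L2-regularized logistic-regression classification with group-aware
    cross-validated (C, N) grid search, exact SHAP attribution for linear
    models, probe-variable relevance selection with resampled rank nulls,
    and Jaccard comparison of retained descriptor sets across datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
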