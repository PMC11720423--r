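Package: digera
Title: Drug-Induced Gene Expression Ranking Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts drug-induced rankings of the 978 L1000 landmark genes
    from chemical structure, cell-line and experimental-condition features,
    and composes multi-objective virtual-screening scores for candidate
    molecules. Provides profile filtering and duplicate resolution, k-means
    outlier screening, rank/tier transformation of Z-score profiles,
    fingerprint and molecular-graph featurization, multi-output random-forest
    and neural sequence/graph rank predictors trained with a listwise
    rank-cosine loss, Voting/Lasso/Ridge/ElasticNet stacking ensembles,
    F1@K ranking evaluation, connectivity-map style Spearman signature
    matching, activity labeling and classification, the Muegge drug-likeness
    filter, and clamp-interpolated composite screening scores. A synthetic
    data generator with planted ground truth makes the whole pipeline
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    ranger,
    glmnet,
    xgboost,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
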