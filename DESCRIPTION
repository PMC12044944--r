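Package: stackscreen
Title: Stacked Ensemble Virtual Screening for Imbalanced Bioactivity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ligand-based bioactivity classification for drug discovery under
    class imbalance. Curates ChEMBL-style IC50 activity tables into labelled
    pIC50 datasets, computes five families of SMILES-based molecular
    fingerprints, partitions the majority class into disjoint balanced
    training subsets, trains a matrix of base classifiers (k-nearest
    neighbours, multilayer perceptron, partial least squares, random forest,
    support vector machine, gradient boosting) whose cross-validated
    probability scores form a probabilistic feature vector, selects features
    by random-forest mean decrease in Gini impurity, and fits a support
    vector machine meta-classifier used for evaluation and virtual screening
    of compound libraries. Includes chemical-space diagnostics (Lipinski and
    Veber rules, Mann-Whitney tests, Bemis-Murcko scaffold overlap, Tanimoto
    similarity audits) and a synthetic-data generator so the full pipeline
    runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mixOmics,
    nnet,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
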