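Package: psntopo
Title: Patient Similarity Networks and Topological Features for Clinical
    Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted patient similarity networks from omics
    expression matrices (Pearson correlation rescaled by WGCNA-style soft
    thresholding to a scale-free graph), extracts per-patient topological
    features (twelve weighted-graph centralities plus binary module
    memberships from spectral clustering and a weighted blockmodel), and
    trains small deep neural networks against SVM and random forest
    baselines with stratified splits, class weighting, seeded replicates
    and balanced-accuracy evaluation. Includes a seeded synthetic-cohort
    generator with paired platform views for cross-platform transfer
    experiments, and ANOVA/Tukey machinery for comparing model groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    jsonlite,
    yaml,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet
Config/testthat/edition: 3
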