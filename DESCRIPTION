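Package: charmark
Title: Character-Level Markov Chain Fingerprints for Speech Transcripts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts speech transcripts into 27-dimensional stationary-distribution
    fingerprints of a character-level first-order Markov chain (26 letters plus the
    space character, Laplace-smoothed transition estimates) and screens the
    fingerprints for group differences between dementia and control speakers:
    per-character two-sample Kolmogorov-Smirnov tests with Bonferroni correction,
    k-means clustering with silhouette-based model selection, PCA projection,
    L1-penalized logistic regression with cross-validated ROC-AUC, and
    transition-network rigidity summaries. Includes a calibrated synthetic-corpus
    generator so recovery, calibration and power properties of the whole pipeline
    can be tested without access-restricted clinical corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    igraph,
    cluster,
    zoo,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: StatisticalMethod, Classification, Clustering
RoxygenNote: 7.3.3
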