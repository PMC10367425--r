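Package: mucosanet
Title: Multi-Omics Analysis of Cervicovaginal Inflammation with Bayesian
    Network Consensus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrated analysis of cervicovaginal multi-omics
    cohorts: limit-of-detection filtering and imputation of cytokine and
    metabolite panels, technical-variability filtering of proteomes against
    reference replicates, hierarchical-clustering stratification of
    participants into low/medium/high inflammation groups, metaproteomic
    spectral-count summarization into taxa and KEGG ko-pathway profiles,
    Kruskal-Wallis/Dunn/Benjamini-Hochberg group statistics, and a discrete
    Bayesian network workflow (BDeu scoring, hill climbing with random
    restarts, bootstrap arc strengths, and a threshold-averaged consensus
    network). Includes a synthetic cohort generator with planted group
    effects and a planted dependence DAG so every stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    randomForest,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
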