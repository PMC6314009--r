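Package: symptomnet
Title: Ising Network Analysis of Binary Comorbidity Symptom Data
Version: 0.1.0
Authors@R:
    person("Network", "Methods Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation and structural analysis of symptom networks from
    binary (presence/absence) questionnaire data, aimed at comorbidity
    studies of two co-occurring disorders. Implements nodewise
    L1-penalized logistic regression with extended Bayesian information
    criterion model selection (the eLasso estimator of a binary Ising
    model), walktrap community detection, bridge centrality indices
    (strength, betweenness, closeness) across disorder clusters, and
    nonparametric bootstrap confidence intervals for edge weights. A
    synthetic cohort generator with exact enumeration, exact and Gibbs
    sampling, and marginal-rate calibration provides ground-truth data
    for validation, emulating a two-disorder (11 + 10 symptom) cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
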