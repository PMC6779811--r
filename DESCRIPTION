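Package: ictonet
Title: Brain Network Ictogenicity and Virtual Resection Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates seizure-like transitions on weighted brain networks with
    the canonical theta (SNIC) phase model, quantifies the seizure-generating
    propensity of a network (Brain Network Ictogenicity, BNI) and the effect of
    removing node sets (Set Ictogenicity, SI), and searches for minimal
    maximally-ictogenic sets using exhaustive enumeration, node-ordering
    heuristics, stratified random search and a constrained multi-objective
    genetic algorithm (NSGA-II). Includes functional-network inference from
    multichannel recordings via surrogate-corrected mutual information,
    cohort-level evaluation of suggested versus actual resections (overlap,
    random baselines, exact rank-sum test, ROC), and generators for synthetic
    networks, coupled signals and patient cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
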