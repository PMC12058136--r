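Package: multimorbnet
Title: Multimorbidity Networks, Patterns and Bridging Diseases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Network analysis of multimorbidity from binary chronic-disease
    indicators. Estimates a pairwise conditional-dependence (Ising-type)
    network by nodewise L1-penalized logistic regression with cross-validated
    penalties and AND-rule aggregation, partitions it into multimorbidity
    patterns by fast-greedy modularity maximisation, scores diseases with six
    centrality metrics to nominate bridging diseases, assigns individuals to
    patterns and to a complex (multisystem) phenotype, and quantifies
    bridging-disease effects on the complex phenotype via gender-stratified
    logistic regression. Includes a synthetic-cohort generator that samples
    binary disease vectors from planted-structure pairwise Markov random
    fields by Gibbs sampling, so the full pipeline is testable without survey
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
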