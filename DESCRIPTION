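Package: pensna
Title: Genetic Analysis of Social Network Aggression Traits in Group-Housed Pigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative-genetic analysis of aggression traits
    derived from social network analysis of group-housed pigs. Builds
    per-pen undirected aggression networks from fight and bullying records
    and computes node centrality traits (degree, betweenness, closeness,
    eigenvector, local clustering, clique membership); constructs the
    pedigree numerator relationship matrix and its sparse inverse; fits
    Bayesian linear and threshold-liability animal models with additive
    genetic and common pen environmental effects by Gibbs sampling;
    summarises posterior draws into heritabilities, pen effects, genetic
    correlations, highest-posterior-density intervals and estimated
    breeding values; and predicts correlated selection response on skin
    lesion traits under truncation selection at the individual and pen
    level. A synthetic-data generator emulates the two-generation pedigree,
    pen structure and trait architecture of a post-mixing aggression study
    so the full pipeline can be exercised and validated without access to
    the original records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    Rcpp,
    coda,
    yaml,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
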