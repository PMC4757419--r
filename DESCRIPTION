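Package: netillusion
Title: The Majority Illusion in Networks: Measurement, Engineering, and
    Analytic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures and analytically predicts the "majority illusion": the
    fraction of nodes in an undirected network that observe a strict local
    majority of neighbors carrying a binary attribute that is globally rare.
    Provides the empirical network statistics the prediction consumes (degree
    distribution, neighbor degree distribution, joint degree distribution
    e(k,k'), degree assortativity, degree-attribute correlation), a binomial
    mixture model of the illusion with a Gaussian closed-form approximation,
    generators for power-law configuration-model and Erdos-Renyi graphs,
    degree-preserving edge rewiring that steers assortativity (and a variant
    that alters e(k,k') at fixed assortativity), attribute swapping that
    steers the degree-attribute correlation, a linear-threshold cascade
    demonstrator, and a sweep harness producing tidy tables of empirical
    versus predicted illusion magnitude.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
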