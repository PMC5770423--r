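Package: cliquenet
Title: Hopfield Networks with Robust Exponential Clique Memory
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Binary Hopfield (McCulloch-Pitts) attractor networks that store
    all k-cliques of a graph as noise-tolerant fixed points. Provides
    asynchronous threshold dynamics with energy descent, minimum probability
    flow (MPF) learning of weights and thresholds (full quasi-Newton fitting
    and the local synaptic update rule), the permutation-symmetric
    three-parameter network family with its closed-form flow minimizer and
    large-deviation robust settings, exact r-stability certificates and
    clique-range feasibility analysis, combinatorial limits for
    permutation-storing (Hopfield-Platt) networks, and seeded experiment
    drivers for error-correction and hidden-clique recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
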