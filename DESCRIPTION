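Package: nichesync
Title: Active-Inference Simulation of Organism-Niche Synchrony and Ecological Inheritance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates reciprocal free-energy minimization between coupled
    active-inference agents that share a Markov blanket. Agents carry
    hierarchical dynamic generative models (two-level chaotic birdsong
    models in generalized coordinates of motion), perceive by gradient
    flows on a Laplace-approximated variational free energy, act by
    voicing their predictions, and slowly learn order parameters of their
    models. The package quantifies identical and generalized synchrony
    between agents, scores organism-niche complementarity as summed free
    energy, and runs duet, teacher-learner (precision asymmetry) and
    niche-inheritance experiments with fully seeded, reproducible outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
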