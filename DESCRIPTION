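Package: coopadapt
Title: Evolution of Cooperative Adaptive Responses in Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates sigmoidal (Glass-type) gene expression dynamics on
    ternary signed regulatory networks and evolves network topology with a
    genetic algorithm under a single-target adaptive-response fitness.
    Provides the step-input response protocol, per-gene adaptiveness metrics
    (response peak minus steady-state shift), average adaptiveness across
    non-terminal genes, signed three-node motif censuses with random
    baselines, robustness analyses (single-edge deletion, Langevin expression
    noise, noisy selection), parameter sweeps, and exhaustive enumeration of
    small networks, so that the emergence of cooperative adaptive responses
    in networks with many genes can be reproduced and studied at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
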