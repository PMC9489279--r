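Package: OrsayHostRange
Title: Phylogenetic Analysis of Orsay Virus Host Range in Caenorhabditis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Benchmark-based susceptibility calling from qPCR Ct data,
    serial-passage transmission scoring, Bayesian phylogenetic mixed-effects
    models (binomial-logit and Gaussian liability models with
    parameter-expanded priors and a Gibbs/Metropolis sampler), and DIC-based
    model and component comparison, for host-range analysis of Orsay virus
    across the Caenorhabditis phylogeny. Includes a synthetic-data generator
    producing trees, Ct tables, observation tables and passage trajectories
    with the statistical structure the models assume, and a pipeline driver
    that reproduces the full analysis from a configuration list.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    MASS,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
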