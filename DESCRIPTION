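Package: mmsm
Title: Multiscale Markov State Models with Adaptive Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Build and analyse multiscale Markov state models (mMSMs): a
    nested hierarchy of Markov state models sharing one trajectory source,
    where each level partitions the states of the level below and is
    estimated at a geometrically growing lag time. Provides online
    K-centers discretization of feature trajectories, bottom-up
    coarse-graining of transition matrices by stationary-weighted lumping,
    modularity-based detection of temporal communities at every timescale,
    and multiscale adaptive sampling that steers new short simulations
    toward under-explored states. Ships synthetic benchmark systems with
    analytic ground truth (overdamped Langevin dynamics on a nested
    multi-minimum potential, nested-block Markov chains), thermodynamic and
    kinetic read-outs (stationary distributions, relaxation and implied
    timescales, free energies, native-contact fractions), streaming
    ingestion of external feature trajectories, and JSON/GraphML
    serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
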