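Package: glomsim
Title: Passive Compartmental Models and Synapse-Count Statistics for
    Olfactory Glomerular Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how synapse-level wiring variation shapes
    circuit function in an olfactory glomerulus. Generates synthetic
    projection-neuron (PN) dendrites and olfactory receptor neuron
    (ORN) to PN connectivity with realistic statistical structure, reads
    and writes SWC skeletons, converts wireframes to cylinder-cable trees
    and discretizes them by electrotonic length, simulates passive
    synaptic responses (mEPSPs, uEPSPs, attenuation, input resistance,
    summation efficacy) with an implicit tree solver, computes wiring
    statistics on ORN-by-PN synapse-count matrices (normalized
    contributions, ipsi/contra asymmetry, cross-PN weight correlations),
    provides permutation tests and synapse shuffling/equalization
    controls, and runs ideal-observer odor-detection and lateralization
    classification experiments on time-averaged PN voltage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
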