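Package: seqspeed
Title: Speed-Controllable Sequence Retrieval in Recurrent Networks with
    Heterogeneous Hebbian Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build recurrent network models that store a sequence of
    random patterns through Hebbian plasticity rules with a per-neuron degree
    of temporal symmetry, and to study how external inputs control the speed
    at which the stored sequence is retrieved. Provides sparse connectivity
    construction for homogeneous, two-population and continuum-symmetry
    networks with bilinear or thresholded plasticity functions; a firing-rate
    simulator with configurable external-input protocols and
    Ornstein-Uhlenbeck input noise; pattern-correlation, retrieval-speed and
    dynamical-regime metrics with phase-diagram sweeps; the corresponding
    mean-field theory (gain functions, overlap dynamics, the speed-symmetry
    law and the retrieval-feasibility condition); a perturbation-based
    reward-driven rule that learns external inputs achieving a target
    retrieval speed; and a leaky integrate-and-fire excitatory/inhibitory
    spiking implementation of the same storage scheme.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
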