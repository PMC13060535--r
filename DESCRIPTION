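Package: ppcgate
Title: Context-Dependent Gating of Sensory Responses in Parietal Cortex
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline and circuit model for context-dependent
    gating of sensory responses in posterior parietal cortex. Provides a
    trial-structured container for two-photon calcium-imaging activity
    built on SummarizedExperiment, a synthetic-session generator with
    planted effect structure, fluorescence preprocessing (neuropil
    correction, rolling-percentile dF/F, AR(1) event extraction),
    sound/photostimulation/engagement modulation indices with
    shuffle-based significance and functional classification,
    population-activity axes with cross-validated projections, linear
    population decoding and single-neuron information estimates, and a
    stochastic excitatory-inhibitory spiking network model that
    reproduces selective enhancement of task-relevant and suppression of
    task-irrelevant inputs in the engaged state.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
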