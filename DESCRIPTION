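Package: mrilnet
Title: Two-Compartment Neuron Networks Learning by Minimization of
    Regularized Information Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulator for competitive networks of two-compartment
    (somato-dendritic) model neurons whose feedforward synapses learn by
    minimization of regularized information loss (MRIL): an online,
    self-supervised rule that minimizes the Kullback-Leibler divergence
    between the Poisson spike distributions implied by the somatic and the
    attenuated dendritic membrane potentials.  Lateral inhibition between
    output neurons is shaped by a symmetric anti-Hebbian spike-timing-
    dependent plasticity rule.  The package includes generators for the
    stimulus classes used to study the model (frozen spatiotemporal spike
    patterns, character-chunk sequences, community-structured random walks,
    oriented-bar images, and correlated harmonic sources mixed for blind
    source separation), evaluation metrics (selectivity assignment,
    reference-response correlation, principal-component variance, negentropy,
    source-separation scores), and ready-to-run experiment presets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
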