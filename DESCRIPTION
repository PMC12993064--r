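Package: calplast
Title: Calcium Diffusion and Threshold-Based Heterosynaptic Plasticity in
    Dendrites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Biophysical simulator of free calcium dynamics in a dendritic
    shaft and its spines, coupled to a two-threshold calcium rule for synaptic
    weight change. Calcium enters a stimulated spine through a representative
    synaptic conductance, exchanges with the dendrite at rates set by
    mean-first-passage times across the spine neck, diffuses along the shaft,
    and drives homo- and heterosynaptic potentiation or depression at
    neighbouring spines. The package provides the implicit (backward Euler)
    reaction-diffusion solver, stimulation-protocol builders, a random
    spine-arrangement generator, a passive cable with a somatic integrator for
    input-sequence selectivity, and drivers for timing-window, multi-spine and
    diffusion-constant sweep experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
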