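Package: addsim
Title: Simulation of Agency-Modulated Dopamine Circuits and Decision Making
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Spiking-network simulator of the ADDS (Agency Disinhibits the
    Dopamine System) circuit, in which a scalar sense-of-agency input
    disinhibits ventral tegmental area (VTA) dopamine neurons through a
    ventral subiculum - nucleus accumbens - ventral pallidum chain, while
    reward-prediction errors reach the VTA through pedunculopontine
    (excitatory) and rostromedial tegmental (inhibitory) drives. Provides
    Izhikevich medium-spiny and quadratic integrate-and-fire neuron models
    with bias-current calibration, silent/tonic/phasic classification of
    dopamine neurons, conversion of spike trains to extracellular dopamine
    concentration traces (fast accumbens and slow cortical clearance
    kernels), packaged in-silico activation protocols with multi-seed
    permutation statistics, and a neuroeconomic decision layer:
    agency-dependent prospect-theory utility, probability weighting,
    gamble evaluation, and hyperbolic temporal discounting with a U-shaped
    dopamine coupling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
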