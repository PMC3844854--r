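Package: pallidalnet
Title: Conductance-Based Network Model of the Parkinsonian Globus Pallidus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a network of single-compartment Hodgkin-Huxley model
    globus pallidus (GP) neurons driven by slow-wave-modulated stochastic
    subthalamic (STN) spike trains, with mutual GABAergic inhibition,
    double-exponential conductance synapses, and activity-dependent
    (calcium-gated) downregulation of HCN channel conductance. Includes an
    adaptive Runge-Kutta-Fehlberg integrator with synaptic event handling,
    an integrate-and-fire style STN spike-train generator, and analysis
    tools: phase categorization of neurons relative to the slow-wave cycle
    (TA/TI/NM/QU), firing statistics, phase histograms, and
    Brillinger-normalized auto/cross-correlograms with confidence bounds.
    Experiment runners reproduce healthy and Parkinsonian (6-OHDA-like)
    network conditions, HCN-knockout and downregulation-ablation protocols,
    network scaling, and a beta-band input variant.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    withr,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
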