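Package: glyqsp
Title: Quantitative Systems Pharmacology of Glycine-Modulated
    Excitation-Inhibition Balance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Mechanistic circuit model of negative symptoms in
    schizophrenia centred on glycine modulation of the NMDA receptor
    co-agonist site. Implements Hill-equation pharmacodynamics for the
    NR2 subunit classes segregated on pyramidal-pyramidal versus
    pyramidal-interneuron synapses, the thermodynamic ceiling on
    extracellular glycine set by the electrogenic 2Na+/Cl-/glycine
    cotransporter GlyT1, a conductance-based cortical
    excitatory-inhibitory spiking network with schizophrenia pathology,
    a dopamine-modulated medium spiny neuron model of the ventral
    striatum, a Balloon-model BOLD readout, steady-state receptor
    competition pharmacology, calibration of a composite imaging proxy
    against PANSS-negative outcomes, and range-based sensitivity
    analysis. Reproduces the inverse U-shaped glycine dose-response
    mechanism arising from the e-i over e-e NMDA current ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
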