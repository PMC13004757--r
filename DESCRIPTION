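Package: mmnsim
Title: Spiking Network Simulation of Auditory Novelty Detection
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Clock-driven simulation of leaky integrate-and-fire networks
    with conductance-based AMPA/NMDA/GABA synapses, short-term synaptic
    depression, and pair-based spike-timing-dependent plasticity (STDP).
    Provides a nine-population novelty-detection (mismatch-negativity-like)
    network with four oddball protocols (frequency deviant, stimulus
    omission, duration deviant, inverse duration deviant), phase-locked
    pacemaker inputs, deviance-detection metrics with an acceptance
    criterion, full-factorial parameter grid search, a synfire chain whose
    STDP feedback synapses entrain to rhythmic stimulation, and
    schizophrenia-associated perturbations (membrane-capacitance increase
    derived from f-I curve areas, reduced excitatory conductance) with a
    fitted cortical output population and group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
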