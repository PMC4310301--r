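Package: stpnet
Title: Error-Driven Learning of Short-Term Synaptic Plasticity in Recurrent Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for recurrent networks of conductance-based
    integrate-and-fire neurons whose synapses carry Tsodyks-Markram
    short-term plasticity (STP) and a triplet spike-timing-dependent
    plasticity (STDP) rule, together with error-driven gradient rules that
    adapt the STP parameters (synaptic utilization U, recovery time
    constant tau_rec, facilitation time constant tau_facil) and the maximum
    synaptic strength A toward a population firing-rate target. Includes
    the sequential wave-stimulus protocol, single- and double-population
    network builders, a mean-field validation layer, connectivity-motif
    symmetry analysis with a Monte-Carlo null model, and projection-group
    summaries of the emergent synaptic subtypes.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
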