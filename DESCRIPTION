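Package: kv1relay
Title: Two-Compartment Thalamocortical Relay Neuron Model with
    Kv1-Dependent Intrinsic Excitability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Conductance-based (Hodgkin-Huxley) simulation of a dorsal
    lateral geniculate nucleus (dLGN) relay neuron as two coupled
    isopotential compartments (somato-dendritic and axonal), featuring a
    low-threshold, slowly inactivating D-type (Kv1) potassium current
    alongside classical thalamocortical currents (transient Na, delayed
    rectifier, A-type, T-type Ca, HCN, leak).  Provides current- and
    voltage-clamp protocol execution with a fixed-step exponential-Euler
    integrator, electrophysiological feature extraction (rheobase, input
    resistance, first-spike latency, spike threshold from phase plots,
    interspike-interval adaptation, latency jitter), differential-evolution
    calibration of maximal conductances and half-activations against
    feature targets, in-silico monocular-deprivation / dendrotoxin /
    intrinsic-plasticity condition experiments, and a seeded surrogate
    recording generator for testing feature extraction and parameter
    recovery without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
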