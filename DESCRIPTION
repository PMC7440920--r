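Package: tcreplay
Title: Thalamocortical Network Simulation of Sleep Replay and Sequence Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based (Hodgkin-Huxley) simulation of a minimal
    thalamocortical network that learns spike sequences through
    spike-timing-dependent plasticity in an awake-like state and
    consolidates them during simulated slow-wave (N3) sleep.  The package
    provides the network builder (topographic, radius-limited
    connectivity), single-neuron and synapse models (AMPA/NMDA/GABA
    kinetics, miniature PSPs, short-term depression, STDP), arousal-state
    switching via neuromodulator scaling, stimulation protocols for
    sequence training and testing, and an analysis suite: recall scoring
    by string match, Up/Down-state detection, sequence replay counting,
    per-synapse replay reliability, synaptic input asymmetry and
    directionality indices, and connection-class statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
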