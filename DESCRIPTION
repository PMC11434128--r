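Package: somnotc
Title: Conductance-Based Thalamocortical Network Simulation of Sleep Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a thalamocortical network of two-compartment cortical
    pyramidal and inhibitory neurons and one-compartment thalamocortical relay
    and reticular neurons with Hodgkin-Huxley-style intrinsic currents,
    kinetic synapses with short-term depression and miniature EPSPs, and a
    scheduled neuromodulatory drive (acetylcholine, histamine, GABA) that
    switches the network between wake, N2, N3 and REM regimes. Provides two
    local field potential forward models (summed intracellular voltage and a
    point-source transfer-resistance model of transmembrane currents),
    spectrogram and band-power analysis, reduced desk-scale fixtures, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    yaml,
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
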