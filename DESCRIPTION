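Package: rosnn
Title: Rank-Order Spiking Network Classification for Electronic-Nose Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spike-latency encoding and continuous classification of
    multivariate gas-sensor-array (electronic nose) data. Steady-state sensor
    responses are converted to spike latencies (ln R / gamma) and rank-order
    signatures; a software simulation of a restricted-Coulomb-energy (RCE)
    nearest-neighbour spiking network with active-influence-field learning
    classifies the signatures under radial-basis-function (RBF) or k-nearest
    neighbour readout with winner-takes-all ordering. Per-class reference
    signatures are derived by probabilistic rank-score coding, and an
    increasing pattern-matching window provides a classification result with
    every incoming spike, including open-set detection of unknown (anomalous)
    signatures. A seeded generator of synthetic metal-oxide array exposures
    with power-law concentration response, latency jitter and drift supports
    fully reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
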