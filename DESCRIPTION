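Package: presynaptic
Title: Hybrid Markov-Mass-Action Modelling of Calcium-Triggered Vesicular Release
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models cell activation by rare binding events at a presynaptic
    terminal. A deterministic mass-action description of the bulk calcium pool
    (free ions, reversible buffering, escape through the terminal neck) is
    coupled to per-vesicle pure-birth Markov chains that count calcium ions
    accumulating on small ribbon targets until a release threshold is reached.
    Includes a simplified Hodgkin-Huxley model of the action-potential-evoked
    calcium influx, narrow-escape rate formulas for the transport rates,
    Brownian-dynamics estimation of how ions entering through channels split
    between targets and bulk, an exact Gillespie stochastic simulator used to
    validate the hybrid model, and an experiment driver that reproduces the
    buffer-sweep release-time distributions.
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
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
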