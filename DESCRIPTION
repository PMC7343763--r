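Package: ddlswitch
Title: Stochastic Dynamics and Energy Dissipation of a Double-Deck-Loop Gene Switch
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Exact and numerical analysis of a two-state (on/off) gene switch
    coupled to the birth-death kinetics of a repressor protein (ROCK), the
    "double-deck loop" model of signal-controlled gene expression. Provides
    closed-form stationary distributions in terms of confluent hypergeometric
    functions, an independent chemical-master-equation solver (null space and
    transient propagation), an exact Gillespie simulator, steady-state entropy
    production with its decomposition into synthesis-degradation and
    gene-switching contributions, and Mode I/II phase-plane analysis with the
    gene-state dominance factor.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
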