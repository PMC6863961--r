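Package: photocure
Title: Kinetics of Radical-Mediated Photopolymerization with Oxygen
    Inhibition
Version: 1.0.0
Authors@R:
    person("Photocure", "Developers", email = "photocure@example.org",
           role = c("aut", "cre"))
Description: Kinetic modeling of radical-mediated (type-I) and singlet-oxygen
    (type-II) photopolymerization of thick films. Implements the full
    seven-species reaction system coupled to dynamic (photobleaching)
    Beer-Lambert light transport, its quasi-steady-state reductions, and
    closed-form expressions for conversion efficacy, oxygen induction time,
    curing depth, and inhibition zone. Includes conversion-dependent
    (viscosity/gel effect) rate constants, figure-caption parameter presets,
    scaling-law diagnostics, and a command-line interface for reproducible
    simulation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
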