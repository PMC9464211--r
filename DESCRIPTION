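Package: hdrefill
Title: Whole-Body Simulation of Vascular Refilling During Hemodialysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Lumped-parameter model of the cardiovascular system coupled to
    whole-body water and solute transport during hemodialysis. Transcapillary
    exchange follows the classic Starling principle extended to a three-pore
    capillary wall (large pores, small pores, aquaporins) with albumin and
    globulin oncotic pressures, small-solute osmosis, interstitial
    pressure-volume and lymph-flow laws, a dialyzer with ultrafiltration and
    two blood-priming procedures. On top of the simulator the package computes
    the vascular refilling rate and the refilling coefficient Kr(t), decomposes
    the Starling forces driving refilling, screens the local relative
    sensitivity of Kr to every model parameter, and emulates hematocrit-based
    clinical estimation of Kr from synthetic measurement series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
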