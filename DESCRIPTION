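Package: woundcpm
Title: Multiscale Cellular Potts Simulation of Dermal Wound Healing with
    Senescent-Cell Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A two-dimensional Cellular Potts model of the proliferative and
    remodelling phases of dermal wound healing, coupled to reaction-diffusion
    fields for PDGF, CSF1, MMP and inflammatory SASP. Fibroblasts activate,
    differentiate into myofibroblasts, deposit extracellular matrix and become
    senescent through primary (CCN1-like), juxtacrine and paracrine routes; the
    senescence programme switches from a fibrogenic to a fibrolytic secretory
    phase. The package provides scenario presets for healthy, fibrotic and
    chronic-wound outcomes, an outcome classifier, a sensitivity sweep over the
    senescence probability and onset-time parameters, and multi-swarm particle
    swarm optimisation for threshold calibration against reference time series.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
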