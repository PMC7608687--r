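Package: morphoswitch
Title: Morphogen-Gradient Interpretation by a Synthetic Bistable Circuit
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling how a synthetic mutual-inhibition (toggle
    switch) gene circuit in E. coli interprets dynamic gradients of the
    quorum-sensing signals 3O-C6-HSL and 3O-C12-HSL. Provides an ODE model
    of the Exclusive Receiver circuit and its Receiver and Relay variants,
    equilibrium and saddle-node continuation analysis to map the bistable
    region in signal space, simulation of the conditioning/exposure
    hysteresis protocol, a 1D reaction-diffusion simulator for transient
    antiparallel and relay-generated gradients, detection and
    classification of expression-domain boundaries from kymographs,
    ratiometric promoter-activity extraction and staged parameter
    inference from plate-fluorometer timecourses, and synthetic-data
    generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    numDeriv
Config/testthat/edition: 3
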