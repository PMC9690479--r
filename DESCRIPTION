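Package: bioheatr
Title: Multi-Segment Human Bioheat Simulation for Asymmetric High-Temperature
    Environments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates whole-body human heat transfer and thermoregulation
    with a 105-node passive system (15 cylindrical segments, each with core,
    artery and vein nodes plus four angular skin sectors) coupled to an
    active controller (vasomotion, sweating, shivering) extended for
    high-temperature exposure: a metabolic multiplier above 39 degrees C
    ambient, dehydration-modified sweating, and a dehydration-driven
    heart-rate increment. Boundary exchange resolves per-sector convection,
    evaporation and two-part radiation with analytic view factors for planar
    radiant sources, enabling staged, angularly non-uniform exposure
    protocols. Includes scenario fixtures for a uniform four-stage 29/45
    degrees C protocol and a warm-wall asymmetric radiation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
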