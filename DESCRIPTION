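Package: ductflow
Title: Pressure-Flow Analysis of Single-Valve Lymphatic Duct Segments
Version: 0.1.0
Authors@R:
    person("Bench", "Analyst", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decomposes bench-measured hydraulic resistance of ex vivo
    thoracic-duct segments into connector, vessel (Poiseuille) and valve
    contributions, fits a sigmoidal valve-resistance model together with an
    exponential valve-pressure map, validates fits by forward flow
    prediction, and computes the valve-opening pressure threshold. Includes
    a rigid-phantom calibration workflow for the connector resistance, a
    self-consistent synthetic bench-data generator with known ground truth
    for end-to-end verification, and a command-line interface for the
    calibrate/analyze/simulate/validate pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
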