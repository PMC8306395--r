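Package: smrkit
Title: Single-Molecule Recycling Simulation and Diffusivity Estimation
Version: 0.1.0
Authors@R:
    person("smrkit", "developers", email = "smrkit@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for single-molecule recycling (SMR) in a
    capillary microchannel. Simulates a fluorescent molecule diffusing in one
    dimension while a piezo stage, driven by a feedback controller, translates
    the capillary back and forth through a fixed confocal laser focus after
    each fixed reversal delay. Provides Gaussian matched-filter (weighted
    sliding sum) photon-burst detection, multi-tau photon autocorrelation with
    a one-dimensional flow-plus-diffusion model fit for translation-speed
    calibration, and a maximum-likelihood estimator of the diffusion
    coefficient from the reconstructed per-cycle molecule positions, with the
    3-sigma transit-time cycle filter.  Includes command-line entry points and
    plain-text file formats for all intermediate data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
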