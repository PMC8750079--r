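Package: minibeamr
Title: Magnetically Converged Proton Minibeam Radiotherapy Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale modelling of proton minibeam radiation therapy (pMBRT)
    delivery with dipole or in-phantom (MRI-like) magnetic fields. Provides
    proton kinematics and range-energy relations in water, multislit collimator
    and pencil-beam-scanning spot-grid geometry, Runge-Kutta tracking of
    minibeam central axes slowing down in uniform magnetic fields, per-slit and
    per-energy field-strength optimization that converges an enlarged minibeam
    array onto a reference transverse dose pattern at the Bragg peak, a
    beamlet-superposition dose engine on a water-phantom voxel grid,
    spatial-fractionation dosimetry metrics (peak-to-valley dose ratio, valley
    dose, flat-region discrepancy, Bragg-peak retraction), and genetic-algorithm
    optimization of spread-out Bragg peak energy-layer weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
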