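Package: braggdose
Title: Small-Field Proton Dosimetry Simulation and Detector Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating small-field proton radiosurgery dosimetry at
    desk scale. Provides a parametric pristine Bragg peak and spread-out Bragg
    peak (SOBP) generator calibrated by distal D50 and 80-20% falloff, erf-edge
    lateral profiles, voxelized dose grids, and a stochastic single-event energy
    deposition sampler for microdosimetric analysis. Models silicon diode and
    plane-parallel ionization chamber detectors (sensitive-volume footprints,
    volume averaging, water-equivalent window offsets, edge-on orientation) and
    the diode charge readout (linearity offset, sensitivity decay with
    accumulated dose, orientation factor, optional LET over-response). Extracts
    standard profile metrics (distal D50, FWHM, FW90M, 20-80% penumbra, SOBP
    90-90% bounds, flatness), computes frequency- and dose-weighted mean lineal
    energies, and reproduces detector-comparison analyses: dose-ratio curves
    versus depth with distal-edge interpolated ratios, misalignment shift
    sensitivity, calibration parameter-recovery fits, and agreement tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
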