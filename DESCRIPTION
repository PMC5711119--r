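Package: beamcal
Title: Sensitivity Calibration of 2D Detector Arrays by Beam-Profile
    Reconstruction with Error-Locking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calibrates per-detector radiation sensitivities of a
    two-dimensional detector array (e.g. a diode array used for
    radiotherapy quality assurance) from wide open-field irradiations at
    unshifted and shifted array positions.  The sensitivity-free 2D beam
    profile is reconstructed iteratively from ratios of shifted to
    unshifted measurements; multiplicative propagation errors caused by
    machine output variation and array positioning inaccuracy are
    estimated from narrow-field triad irradiations and removed by an
    error-locking scheme.  A noniterative scan-based reference method, a
    full measurement simulator with known ground truth, text file formats
    and a command-line interface are included so every stage can be
    exercised without access to a linear accelerator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
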