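Package: puretone
Title: Smartphone Pure-Tone Audiometry: Staircase Threshold Search, RETSPL
    Calibration and Virtual-Listener Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements air-conduction pure-tone audiometry as performed by a
    calibrated smartphone-earphone combination: the modified Hughson-Westlake
    "10 dB down, 5 dB up" adaptive staircase with a three-reversal stopping
    rule, conversion between hearing level (dB HL) and sound pressure level
    (dB SPL) through reference equivalent threshold sound pressure level
    (RETSPL) tables, ASHA audiogram severity classification, interaural
    attenuation masking arithmetic, calibrated pure-tone and narrow-band
    masking-noise synthesis, and a median-difference procedure that corrects a
    device RETSPL table from paired audiometer/device threshold measurements.
    A virtual-listener simulator with deterministic and logistic psychometric
    response models lets the full test-calibrate-evaluate loop run without
    human subjects or audio hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
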