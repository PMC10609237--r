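Package: pindrop
Title: Image-Sensed Droplet Volumetry and Feedback-Controlled Nanoliter Dispensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the volume of sessile nanoliter droplets from top-view
    grayscale images and simulates model-based feedback control of a contacting
    (pin-based) liquid dispenser. Images are median filtered, segmented by Otsu
    thresholding, and reduced to a calibrated pixel area; volume follows from a
    spherical-cap model parameterised by the fluid contact angle and a
    reference-point pixel-to-millimetre scale. An empirical dispense law
    calibrated on a velocity-by-depth grid drives a closed-loop simulator that
    holds a volume setpoint against reservoir-level drift, with an open-loop
    baseline for comparison. A synthetic bench renders droplet and fiducial
    images with known ground truth so the full pipeline is testable without
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    tiff,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
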