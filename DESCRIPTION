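Package: holoquant
Title: Smartphone Colour Quantification for Holographic Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: End-to-end colour quantification of holographic biosensor
    photographs: passcode-based image encryption and single-level wavelet
    compression for secure transfer, feature-based localisation of a QR
    fiducial carrying the sensor, camera characterisation (per-channel gamma
    linearisation, flat-field correction and polynomial RGB-to-CIEXYZ
    regression selected by median CIE76 colour difference), automatic
    colour-cluster segmentation driven by the Turi-Ray validity measure,
    Fisher-separability ranking of colour spaces, self-organising-map
    recognition of the sensor region, method-agreement statistics
    (intraclass correlation, Bland-Altman limits) and multilayer-perceptron
    calibration of the nine-dimensional hybrid colour descriptor to analyte
    concentration (pH). A parameterised scene/camera simulator generates
    fully ground-truthed synthetic imagery for testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    grDevices,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
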