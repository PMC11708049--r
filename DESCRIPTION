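Package: colidist
Title: Spatial and Flow-Cytometric Quantification of Colibactin-Induced
    DNA Damage Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the bacterial SOS/recA DNA-damage response around
    colibactin-producing colonies. Implements half-maximal decay distance
    (dist50) estimation from fluorescence cross-section profiles of
    multichannel plate microscopy (contacting and non-contacting colony
    variants), flow-cytometry gating with three-standard-deviation
    percent-positive classification, replicate-level Welch tests, and CFU
    back-calculation from serial dilutions. A synthetic-data generator
    renders multichannel plate scenes with an exponentially decaying toxin
    field and samples log-normal flow-event mixtures with ground-truth
    labels, so every analysis stage is testable against a known parameter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
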