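Package: fermsense
Title: Soft-Sensor Calibration for Sourdough Fermentation from Gas Sensor Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for online monitoring of sourdough fermentation with a pulsed
    metal-oxide gas sensor array. Provides a seeded simulator of fermentation
    kinetics (sigmoid pH drop, near-linear rise in total titratable acidity) and
    of the pulsed three-channel sensor signal; segmentation of raw traces into
    five-minute measurement cycles with peak-height, peak-area and baseline
    extraction; three calibration methods mapping sensor information to pH or
    TTA (baseline-corrected sensor-signal regression, principal-component
    regression on the six peak features, and interval-PCA scoring of raw cycle
    shapes); error metrics (SSE, RMSE, percentage error of the reference range,
    R squared) on the five-minute evaluation grid; and parameter-transfer
    validation between calibration models, including pooled multi-run models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
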