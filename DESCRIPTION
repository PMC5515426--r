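Package: beatid
Title: Single-Heartbeat ECG Biometric Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies individuals from single-lead electrocardiogram (ECG)
    recordings using three heart-rate-normalized wave-morphology intervals
    (QT, RT, ST) extracted from each heartbeat. Provides Butterworth low-pass
    preprocessing, Pan-Tompkins R-peak detection, derivative-based Q/S/T
    delineation inside physiological search windows, plausibility-based beat
    rejection, a population-mean RR normalization that needs a single stored
    constant, one-against-all radial-basis-function support vector machine
    classification with cross-validated hyper-parameter selection, a
    block-resampling evaluation protocol with false-acceptance and
    false-rejection rates, a beats-to-identification resampling analysis,
    and a synthetic ECG generator with known fiducial ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
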