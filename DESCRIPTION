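Package: drivermon
Title: Driver Physiological Monitoring from PPG and Facial Landmark Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for multi-modal driver-state monitoring.
    Simulates photoplethysmographic (PPG) pulse trains with ground-truth
    fiducial points, facial-landmark intensity series linearly coupled to
    cardiac activity, synthetic eye patches and blood-pressure beat cohorts;
    filters and segments PPG and detects the four per-beat extreme points
    (onset, systolic peak, dicrotic notch, diastolic peak) by derivative
    analysis; reconstructs PPG from the composite landmark signal with an
    LSTM or a dilated temporal convolutional network; scores drowsiness from
    the LF/HF ratio of heart-rate-variability spectra; flags abnormal blood
    pressure from augmentation-index beat features with a shallow neural
    network; implements recurrent criss-cross self-attention with a
    pedestrian-salience bounding-box filter; and fuses all flags through
    rule-based driving-safety risk levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
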