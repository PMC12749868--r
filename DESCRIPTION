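Package: ppgrestore
Title: Restoration of Contact-Pressure-Distorted Photoplethysmography
    Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for restoring the ideal pulse morphology of wrist
    photoplethysmography (PPG) signals distorted by sub-optimal skin-sensor
    contact pressure. Provides a seeded synthetic generator of paired
    (reference, distorted) pulse streams, a five-step preprocessing pipeline
    (zero-phase Butterworth lowpass and DC removal, morphology-based invalid
    segment removal, sliding-window segmentation, per-window min-max
    normalization, and augmentation), per-cycle fiducial point detection
    (systolic peak, dicrotic notch, diastolic peak) with a 30-90% validity
    rule, a U-shaped gated-convolutional encoder-decoder with squeeze-and-
    excitation blocks and a bidirectional LSTM latent stage trained
    adversarially with a hinge discriminator loss and a PPG-aware custom
    loss, waveform evaluation metrics (MAE, dynamic time warping, Pearson
    correlation, fiducial-feature MAPE, skewness/kurtosis errors), and
    downstream heart-rate, heart-rate-variability and blood-pressure feature
    estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
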