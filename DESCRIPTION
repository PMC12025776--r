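Package: ppgqc
Title: Supervised Quality Recognition of Photoplethysmogram Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated quality control of photoplethysmogram (PPG)
    segments. Provides a seeded synthetic PPG generator with controllable
    artifact models (additive noise, baseline wander, motion spikes, clipping),
    a four-stage preprocessing chain (anti-aliased downsampling, moving-average
    smoothing, Butterworth low-pass filtering, min-max scaling), three binary
    quality classifiers built from first principles (a 1D CNN-LSTM, a CNN-MLP,
    and a CNN-KAN whose Kolmogorov-Arnold layers carry learnable B-spline
    activations), and a training harness with stratified splitting, binary
    cross-entropy loss, Adam optimisation, early stopping, grid search by
    validation AUC, and the standard classification metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    data.table,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
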