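Package: apneafuse
Title: Ensemble Detection of Obstructive Sleep Apnea from Single-Lead ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-minute detection of obstructive sleep apnea from
    single-lead electrocardiogram recordings. Implements the full
    pipeline: R-peak detection with a multilevel Teager energy operator,
    beat-series feature extraction (RR intervals, R-peak amplitudes and an
    ECG-derived respiration surrogate) interpolated onto a uniform 240-point
    per-minute grid, three small convolutional base classifiers (two 1-D
    CNNs and a CNN-LSTM) trained with Adam on a built-in neural-network
    engine, and four classifier-fusion rules: majority voting, the sum
    rule, Choquet-integral fuzzy fusion with entropy-derived Sugeno
    lambda-measures, and a trainable multilayer-perceptron stacker.
    Includes a synthetic ECG generator emulating the cyclic heart-rate
    signature of apnea so the whole stack is testable without clinical
    data, readers for WFDB-style and CSV record layouts, and evaluation
    utilities (confusion-matrix metrics, two-fold swap and k-fold
    cross-validation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
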