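Package: eamreg
Title: Registration and Classification of Left Atrial Electroanatomical
    Voltage Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing left atrial electroanatomical voltage maps
    acquired during atrial fibrillation ablation. Point clouds carrying
    unipolar and bipolar voltages are preprocessed (per-map min-max
    normalisation, minimum-point filtering, resampling to a common count),
    aligned to a common template by SE(3) Lucas-Kanade registration through
    a learned permutation-invariant point-cloud feature space, canonically
    reordered by L1 distance to the origin, and classified with a small
    multilayer perceptron under leave-one-out cross-validation, including a
    probability-averaging ensemble of the unipolar and bipolar channels.
    A synthetic cohort generator with ground-truth rigid poses and
    class-dependent low-voltage burden supports end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    Matrix,
    optparse
Config/testthat/edition: 3
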