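Package: wristtremor
Title: Parkinsonian Tremor Detection from Wrist-Worn Accelerometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects Parkinson's disease tremor in triaxial wrist accelerometer
    recordings. Implements the full pipeline: resampling, gravity removal and
    windowing; unsupervised non-negative tremor factorization that splits each
    window's amplitude spectrum into tremor and non-tremor parts over fixed
    sinc-harmonic and Hann dictionaries; hand-crafted feature sets (band energy,
    Welch PSD, a 356-dimensional baseline set, MFCCs, and MFCCs of the factorized
    spectra); random-forest, multi-layer-perceptron and small convolutional
    classifiers; weakly supervised training from 3-level self-report diary labels
    via stratified multiple-instance learning; leave-one-subject-out ROC
    evaluation, weak-label agreement, and percentage-of-tremor-time estimation;
    and a synthetic cohort generator so every stage is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
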