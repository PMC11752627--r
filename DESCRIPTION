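Package: afwave
Title: Time-Frequency Scalogram Analysis and CNN Classification of Single-Lead ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for atrial-fibrillation screening from short single-lead
    ECG recordings via time-frequency images. Reads PhysioNet/CinC 2017-style
    records (MAT sample container plus WFDB-style header), applies
    fixed-duration segmentation with exclusion of short records and
    Fourier-domain resampling, computes short-time Fourier spectrograms and a
    generalized Morse continuous wavelet transform with a from-scratch
    frequency-domain filter bank, renders fixed-size RGB scalogram images,
    trains a transfer-learning-style convolutional classifier with rmsprop and
    validation-accuracy early stopping, and evaluates with per-class and macro
    accuracy, sensitivity, specificity, precision, F1, Matthews correlation,
    ROC/AUC and precision-recall curves. A synthetic four-class ECG generator
    (normal sinus, AF-like, ectopic, noise) makes every stage testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
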