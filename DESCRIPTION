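Package: enosepipe
Title: Electronic-Nose Breath Analysis with a Perceptron Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for thermally cycled metal-oxide-semiconductor
    (MOS) electronic-nose breath records: a synthetic cohort generator
    emulating 16-channel 30 Hz acquisitions with square-wave synchronization
    channels, segmentation of thermal-cycling periods, ratio-based feature
    extraction with downsampling and clinical covariates, a from-scratch
    one-hidden-layer sigmoid perceptron trained by full-batch backpropagation
    with early stopping, and repeated random 5-fold cross-validation
    reporting accuracy, sensitivity and specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    rlang,
    stats,
    utils,
    withr,
    yaml,
    zip
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
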