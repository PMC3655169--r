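Package: curvecad
Title: Curvelet Texture Analysis Pipeline for Pulmonary Nodule Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A computer-aided diagnosis analysis for solitary pulmonary
    nodules on CT, exercised end-to-end on synthetic data: seeded
    region-growing background removal for nodule regions of interest, a
    three-scale FFT-based curvelet-style tight-frame decomposition into 34
    sub-bands, 14 gray-level co-occurrence texture statistics per sub-band
    (476 texture features, 488 model inputs with clinical covariates),
    SMOTE class balancing, radial-basis-kernel support vector machine
    classification with stratified patient-grouped cross-validation,
    patient-level malignance-rate ROC analysis, and longitudinal
    texture-change assessment across repeat scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
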