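Package: ftirdisc
Title: ATR-FTIR Fingerprint Discrimination of Two-Class Herbal Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Chemometrics pipeline for discriminating two closely related
    herbal classes from mid-infrared attenuated total reflectance (ATR-FTIR)
    spectra. Provides a spectral data container with CSV and JCAMP-DX input,
    eleven named pretreatment recipes (scatter correction, derivatives,
    normalizations, airPLS baseline removal), Kennard-Stone
    calibration/validation splitting, random forest, RBF-kernel support
    vector machine and PLS-DA classifiers with out-of-bag and
    cross-validation tuning, permutation-importance variable selection,
    confusion-matrix evaluation (sensitivity, specificity, accuracy,
    Matthews correlation, AUC), class-mean band analysis, and a synthetic
    two-class spectrum generator for end-to-end testing of the workflow.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    signal,
    randomForest,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
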