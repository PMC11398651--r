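Package: dceradiomics
Title: Reproducibility and Predictivity of Radiomic Features on Dynamic
    Contrast-Enhanced CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the reproducibility of radiomic texture
    features extracted from dynamic contrast-enhanced CT (DCE-CT) of liver
    lesions, and for building grade-classification models from the
    reproducible features. Implements a 127-feature extractor (first-order,
    GLCM, run-length, GTDM, Gabor/Laws/LoG/wavelet filter banks, sigmoid edge
    and fractal descriptors) with fixed 25-HU binning, Lin's concordance
    correlation coefficient with inter-observer, inter-sequence and
    intra-phase analyses, Spearman-based pruning of correlated features, a
    SMOTE + recursive-feature-elimination + boosted-tree classification
    protocol, and a synthetic DCE-CT lesion phantom generator so the whole
    chain is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    caret,
    data.table,
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    RNifti,
    rpart,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    ipred,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
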