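Package: mammotrend
Title: Temporal Parenchymal Texture Analysis of Serial Mammograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether longitudinal change in mammographic
    parenchymal texture carries information about future breast cancer risk.
    Provides a synthetic-cohort generator for serial two-breast screening
    exams with a label-dependent temporal texture drift (a "field effect"
    surrogate), a 50-feature parenchymal radiomic bank (fractal, edge,
    histogram, Fourier, power-law, NGTDM and GLCM families), multi-stage
    pooled convolutional features, a long short-term memory (LSTM) sequence
    classifier for variable-length exam histories with zero padding and
    masked binary cross-entropy, a single-timepoint PCA+SVM baseline, and
    ROC machinery (DeLong inference, paired comparisons, Holm-Bonferroni,
    classifier merging) with leakage-safe stratified grouped
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    tiff,
    png,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
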