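Package: dermofuse
Title: Multimodal Feature Extraction and Classification of Skin Neoplasms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts quantitative features from three non-invasive skin
    screening modalities - diffuse reflectance spectra (melanin, erythema,
    hemoglobin, spectral-slope and malignancy indices), optical coherence
    tomography B-scans (first-order statistics, Shannon entropy and
    gray-level co-occurrence Haralick texture features after a threshold /
    erosion / Gaussian denoising chain) and high-frequency ultrasound lesion
    masks (13 shape and size descriptors from a two-annotator consensus
    region) - fuses them into per-observation feature vectors, and trains a
    gradient-boosted multiclass classifier of basal cell carcinoma clinical
    forms versus benign neoplasms under tumor-grouped leave-one-out
    cross-validation, with sensitivity / specificity / precision / F1 / IoU
    reporting, probability-threshold and ROC curves, and feature-importance
    attribution. A seeded synthetic cohort generator emulates all input
    modalities with class-dependent structure so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
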