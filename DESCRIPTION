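Package: sersstroma
Title: Stromal SERS Imaging Metabolomics for Differential Diagnosis of
    Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for hyperspectral surface-enhanced
    Raman spectroscopy (SERS) imaging of breast-cancer biopsies: silicon-line
    wavenumber calibration, asymmetric-least-squares baseline correction,
    pixel binning and band integration; joining of spectra with pathology
    annotation masks and stromal region-of-interest meshes; per-patient
    differential-wavenumber discovery with Welch tests and dominance calls;
    and mesh-level supervised classification (six algorithm families,
    patient-disjoint cross-validation, Cohen's-kappa model selection,
    permutation importance) with mesh-ratio patient aggregation. A seeded
    synthetic tissue-phantom generator emulates annotated cohorts so the
    whole analysis is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    png,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xgboost,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
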