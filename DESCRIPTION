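Package: spacerstrat
Title: Dose-Prediction Decision Support for Rectal Spacer Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-support toolkit for stratifying prostate radiotherapy
    patients for rectal spacer insertion from predicted rectal dose. Provides
    a seeded synthetic pelvic-phantom and analytic three-dose-level plan
    simulator, preprocessing of structure masks and dose grids (spline
    resampling, anatomical cropping, dose normalisation), a five-level 3D
    hierarchically densely connected U-Net dose-prediction model trained with
    Adam on mean-squared error, cumulative dose-volume histogram (DVH)
    extraction, EQD2 fractionation correction, generalized EUD and
    Lyman-Kutcher-Burman normal-tissue complication probability modelling for
    grade-2 late rectal bleeding and late fecal incontinence, prediction
    evaluation (DVH error profiles, isodose Dice similarity, Bland-Altman
    agreement), and four constraint- and risk-based stratification methods
    with confusion-matrix accounting and risk-threshold sweeps.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
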