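Package: nodtex
Title: Quantitative CT Texture Analysis for Discriminating Non-Calcified
    Hamartoma from Lung Adenocarcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible radiomics pipeline for solid pulmonary nodules on
    CT. Reads NIfTI volumes and region-of-interest masks, converts masks to
    per-voxel attenuation lists, normalizes attenuation within mu +/- 3 sigma,
    and extracts a 94-feature panel: 8 three-dimensional attenuation features
    (mass, logistic curve-fit parameters, distribution moments), 80 gray-level
    co-occurrence matrix (Haralick-family) features on four orientations of
    the maximum-area slice at 8 gray levels, and 6 rotation-invariant local
    binary pattern features. Provides Welch t-tests with Bonferroni
    correction, Dice segmentation agreement, ROC/AUC evaluation, and a
    feedforward neural-network classifier assessed by repeated stratified
    k-fold cross-validation, together with a synthetic two-class nodule
    phantom generator for end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
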