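Package: oleasterHSI
Title: Near-Infrared Hyperspectral Imaging Pipeline for Geographical
    Origin Classification of Dried Fruits
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end chemometric pipeline for classifying the
    geographical origin of dried fruits from single-fruit near-infrared
    hyperspectral images (874-1734 nm, 256 bands). Provides a synthetic
    scene generator emulating a push-broom line-scan instrument,
    white/dark reflectance correction, single-band fruit segmentation,
    spectral preprocessing (band cropping, Daubechies-6 wavelet
    denoising, area normalization, per-fruit averaging), effective
    wavelength selection from second-derivative class-mean spectra, and
    three classifiers (PLS-DA via SIMPLS, RBF-kernel SVM with grid
    search, and a one-dimensional convolutional neural network), with
    confusion-matrix reporting over calibration, validation and
    prediction splits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
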