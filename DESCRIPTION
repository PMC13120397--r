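Package: specpoly
Title: Hyperspectral Chemometrics for Nondestructive Seed Polyphenol Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: End-to-end near-infrared hyperspectral pipeline for predicting total
    polyphenol content of intact seeds. Covers white/dark reflectance correction
    of ENVI-format hypercubes, Otsu guide-band segmentation and region-of-interest
    mean-spectrum extraction, spectral preprocessing (MSC, Savitzky-Golay, first
    derivative, SNV), effective-wavelength selection by competitive adaptive
    reweighted sampling (CARS) and the successive projections algorithm (SPA),
    partial least squares and least-squares support vector machine baselines, and
    a multi-scale residual one-dimensional convolutional network (MS-RCNN) with
    Grad-CAM band-saliency interpretation. Includes seeded synthetic-data
    generators so every stage is testable without proprietary instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
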