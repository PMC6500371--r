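Package: sargnet
Title: Deep Classifiers and the Floating Algae Index for Coastal Sargassum
    Detection from MODIS Reflectances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pixel-level presence/absence classification of pelagic Sargassum
    from 14-band MODIS corrected-reflectance vectors (surface and
    top-of-atmosphere reflectance at 412, 469, 555, 645, 859, 1240 and
    2130 nm). Implements the ERISNet convolutional-recurrent architecture
    together with multilayer-perceptron and fully-convolutional baselines,
    trained with a from-scratch 1D convolution / LSTM / batch-normalization
    engine; a stratified split and k-fold cross-validation harness with the
    mean per-class error (MPCE) statistic; the Floating Algae Index (FAI)
    with per-class summary statistics; a reader/validator for labeled
    reflectance pixel tables; and a correlated-Gaussian synthetic pixel
    generator with an analytic Bayes-accuracy oracle so the full pipeline is
    testable without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
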