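Package: grapespec
Title: In Situ VNIR-SWIR Spectroscopy Workflow for Wine-Grape Sugar Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometrics workflow for predicting wine-grape ripeness
    (total soluble solids, degrees Brix) from in-situ VNIR-SWIR reflectance
    spectra (350-2500 nm). Provides a grape spectral-library container with
    CSV I/O and wavelength-grid downsampling; the standard spectral
    pre-treatments (standard normal variate, Savitzky-Golay derivatives,
    pseudo-absorbance, continuum removal) composed into nine named spectral
    inputs; four regression families (partial least squares, random forest,
    support vector regression with radial kernel, and a one-dimensional
    convolutional neural network tuned by Hyperband) behind one fit/predict
    interface; nested 5-fold cross-validation with R-squared, RMSE and RPIQ
    reporting; pre-hoc (mutual information) and post-hoc (VIP, impurity,
    SAGE) wavelength-importance profiles with cross-fold mean ranking; and a
    synthetic grape-spectra generator for end-to-end testing when field data
    are unavailable.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    randomForest,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse,
    yaml
Config/testthat/edition: 3
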