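Package: nircae
Title: Convolutional Autoencoder Calibration for Near-Infrared Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative near-infrared spectroscopy calibration built on a
    one-dimensional convolutional autoencoder. A 700-channel absorbance
    spectrum is compressed to 32 latent variables by an unsupervised
    encoder-decoder network trained with Adam and early stopping; multiple
    linear regression on the latent variables then predicts compositional
    targets such as moisture, oil, protein and starch. The package also
    provides the conventional chemometric baselines the method is compared
    against (standard normal variate, multiplicative scatter correction,
    Savitzky-Golay filtering and mean centering, combined with partial least
    squares and principal component regression with cross-validated component
    selection), evaluation metrics (R-squared, RMSE, RMSPE), a Beer-Lambert
    synthetic spectra generator, and an experiment driver that assembles the
    full benchmark report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    signal,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
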