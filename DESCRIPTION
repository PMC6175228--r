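Package: fastwhiten
Title: Covariance-Component Prewhitening and Functional Sensitivity for
    Rapidly Sampled fMRI Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models and removes serial correlations in rapidly sampled
    fMRI time series.  Builds extended Toeplitz covariance-component
    dictionaries (the FAST family of exponential decays at multiple
    timescales, and the classical AR(1)-plus-white-noise pair), estimates
    mixture hyperparameters by restricted maximum likelihood with Fisher
    scoring on variational free energy, prewhitens the data, and fits the
    general linear model.  Provides the t-score testing for the mean
    signal as a correlation-aware alternative to the weighted temporal
    signal-to-noise ratio, along with an evaluation battery: Ljung-Box
    residual whiteness screening with false-discovery-rate control,
    residual power spectra, precision-stability analysis against the
    square root of the sample count, and free-energy model comparison.
    A block-design BOLD simulator with autoregressive noise and a
    decimation scheme supports calibration and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    RNifti
Config/testthat/edition: 3
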