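Package: bisca
Title: Bispectral Component Analysis of Electrophysiological Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.com",
           role = c("aut", "cre"))
Description: Multitaper estimation of power spectra, bispectra and
    bicoherence of EEG-like time series with sine tapers; robust
    median-based and maximum-based tests that separate system
    nonlinearity from input non-Gaussianity, calibrated with
    autoregressive surrogate data; and a joint parametric decomposition
    of the spectrum and bispectrum into an aperiodic (Xi) background and
    harmonic oscillatory (Rho) peaks, with component-level bicoherence
    decomposition and tests. Includes seeded generators for the four
    reference signal classes (Gaussian/non-Gaussian x linear/nonlinear)
    and an end-to-end multichannel pipeline with EDF and delimited-text
    input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
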