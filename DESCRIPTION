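Package: hhtexcess
Title: Hilbert-Huang Transform Decomposition for Heatwave Excess Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decomposes daily mortality time series with the Hilbert-Huang
    Transform (empirical mode decomposition and its noise-assisted ensemble
    variant), separates trend from non-trend intrinsic mode functions by
    testing observed IMF energies against white-noise and fractional-noise
    energy spectra with 95%/99% confidence bands, and derives epidemiological
    outputs from the resulting partition: excess deaths summed over an event
    window, daily log relative risk, and ordinary least-squares excess-risk
    regressions on temperature and air-pollution covariates. Includes Hilbert
    spectral analysis (instantaneous frequency and amplitude per mode), a
    classical moving-average seasonal decomposition comparator, and synthetic
    generators for mortality-like series with injected heatwave spikes.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
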