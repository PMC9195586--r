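Package: wmchar
Title: Spectral Characterization Methods for Frequency-Domain Weak
    Measurement Polarimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward model and phase estimators for frequency-domain weak
    measurement polarimetry with a broadband (superluminescent diode)
    source.  Implements the two-state polarization algebra (pre- and
    post-selection states, weak values and weak moments), the interference
    readout spectrum, and five spectral characterization methods for
    recovering an optical-rotation phase difference: unweighted and
    source-weighted spectral centroids, a skew-Gaussian weighted centroid,
    a maximum-likelihood estimating equation, a classical intensity-ratio
    inversion, and an implicit transition equation in tan(delta/2) that
    bridges the weak-value and classical readout regimes.  Includes the
    evaluation protocol (calibration curves from stepped phase ramps,
    resolution, linear measurement range), a synthetic generator for noisy
    spectral ramps and sucrose-hydrolysis phase kinetics, and a small
    command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
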