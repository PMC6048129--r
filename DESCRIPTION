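Package: deerfit
Title: DEER and Dipolar CW-EPR Distance Distribution Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of pulsed dipolar EPR (four-pulse DEER/PELDOR) and
    rigid-limit continuous-wave EPR data for spin-labeled proteins. Simulates
    dipolar evolution waveforms from Gaussian distance distributions via the
    Fresnel-integral dipolar kernel, fits and corrects intermolecular
    background, recovers model-free distance distributions by Tikhonov
    regularization with L-curve and leave-one-out cross-validation smoothing
    selection, parameterizes form factors by multistart sum-of-Gaussians
    fitting with Bayesian information criterion model selection and
    error-surface uncertainties, analyzes short-range dipolar broadening of
    CW spectra by Pake-pattern convolution, and computes nitroxide rotational
    correlation times and order parameters from outer-extrema splittings.
    Includes a synthetic-data module emulating calmodulin/RyR-peptide
    experimental conditions for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    pracma,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
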