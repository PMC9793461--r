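Package: ivrkit
Title: In Vitro Release Testing Analytics for Fiber-Optic UV-Vis Dissolution Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for in vitro release (IVR) testing of oil-solution
    parenterals monitored in situ by fiber-optic UV-Vis spectrometry. Converts
    time-resolved absorbance spectra into percent-released profiles by single-wavelength
    calibration or by first-derivative spectroscopy, which cancels spectrally flat
    excipient interference. Includes apparent partition coefficient and sink-condition
    volume calculators, first-order and biphasic release-kinetics fitting, the f2
    profile-similarity factor, and a synthetic spectral-data generator with ground
    truth for validating every pipeline stage without a dissolution instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
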