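Package: nirclass
Title: On-Device Chemometrics for a Handheld NIR Cannabis Classifier
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-implements the complete on-device evaluation chain of a
    handheld near-infrared (NIR) sensor that discriminates legal from
    illegal cannabis samples at a 0.4 wt% THC threshold: triplet-scan
    quality control, white-reference absorbance, Savitzky-Golay
    derivative and Standard Normal Variate preprocessing, interval-PLS
    wavelength selection, NIPALS PLS-DA with Bayes-calibrated class
    probabilities and a 60% uncertainty zone, and dual-sensor decision
    fusion. Includes a synthetic spectra generator that emulates the
    statistical structure of the field data (packaging interference,
    water band, multiplicative scatter, module-to-module variation,
    spot heterogeneity) so the whole pipeline is testable end-to-end
    without any proprietary data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
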