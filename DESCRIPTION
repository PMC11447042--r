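Package: ratiospec
Title: Ratio-Spectra Spectrophotometry for Overlapping Binary Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Resolves two analytes with heavily overlapping UV absorption
    spectra by manipulation of ratio spectra: ratio difference, first
    derivative of the ratio spectra, and mean centering of the ratio
    spectra.  Includes the full calibration and validation statistics
    layer used in pharmaceutical quality control (linearity, LOD/LOQ by
    3.3*sigma/S and 10*sigma/S, recovery, repeatability and intermediate
    precision, standard addition, and two-sample t and variance-ratio F
    method comparison), wavelength and divisor selection scans, and a
    Beer-Lambert synthetic-spectra generator emulating a weak narrow-band
    absorber overlapped by a strong broad-band absorber, as in the
    bisoprolol fumarate / telmisartan fixed-dose combination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
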