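Package: vlmalign
Title: Virtual Lock-Mass Detection, Correction and Alignment for Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Renders batches of centroided mass spectra comparable by
    detecting virtual lock masses (peaks shared by every spectrum of a set,
    found by a heap-based sweep over the pooled peak lists), recalibrating
    each spectrum's m/z axis by piecewise linear interpolation through the
    detected points, and deriving alignment points that convert corrected
    spectra into feature matrices for statistical and machine-learning
    analysis. Includes a brute-force reference implementation of the
    detection definitions, a synthetic-spectra generator with planted
    ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    mzR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
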