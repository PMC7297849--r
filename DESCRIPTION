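Package: anslope
Title: Validity Diagnostics for the Ratio Effect Slope as an ANS
    Sensitivity Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decide when the comparison-task ratio effect slope is
    a valid proxy for the sensitivity (Weber fraction) of the approximate
    number system (ANS). Implements the Gaussian representational model of
    numerical magnitude, exact computation of the representational overlap
    of two magnitudes (the integral of the pointwise minimum of their
    Gaussian densities), ratio-effect curves and expected-range indices
    over Weber-fraction intervals, direction classification of the
    slope-sensitivity relation, Monte Carlo simulation of the correlation
    attenuation caused by measuring sensitivity with the slope, and a
    synthetic number-comparison trial generator with maximum-likelihood
    Weber-fraction recovery. A command-line interface reproduces the full
    set of diagnostic tables and distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
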