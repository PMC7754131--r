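Package: powerequiv
Title: Bayes Factor Design Analysis and Power-Equivalent Designs for Latent
    Growth Curve Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans longitudinal studies analysed with latent growth curve
    models (LGCMs). Simulates data from an LGCM with fixed nuisance
    parameters, computes the Bayes factor for the test of zero slope
    variance (H0 sigma2_S = 0 against a gamma-distributed alternative) by
    one-dimensional quadrature over the structured multivariate-normal
    likelihood, and runs Monte-Carlo Bayes factor design analyses (BFDA)
    for fixed-N designs. Designs differing in the number of measurement
    occasions and the total study duration can be reduced to a common
    effective error variance; the package solves for equally spaced designs
    that are power equivalent to a reference design, verifies that their
    Bayes-factor distributions agree, and ranks them by study cost.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
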