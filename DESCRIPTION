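Package: ehldrec
Title: Inference for the Exponentiated Half-Logistic Distribution from
    Lower Record Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Point and interval estimation of the shape parameter of the
    exponentiated half-logistic distribution when the data are lower record
    values and the reciprocal-scale parameter is a nuisance. Implements
    profile maximum likelihood with Wald intervals from a series expansion
    of the expected Fisher information, pivotal-quantity estimation with
    exact and generalized-pivotal confidence intervals, and Bayesian
    estimation under a vague gamma prior and a uniform-mixed hierarchical
    prior with maximum-a-posteriori plug-in for the nuisance parameter.
    Includes an exact record-value simulator, a Monte-Carlo evaluation
    engine for mean squared error, bias and interval coverage, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
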