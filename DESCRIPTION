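Package: grpseqest
Title: Point Estimation After a Two-Stage Group Sequential Trial
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact, quadrature-based tools for point estimation after a
    two-stage group sequential trial whose standardised test statistics
    follow the canonical joint distribution. Provides the closed-form
    sampling density of the terminal statistic, nine adjusted point
    estimators (maximum likelihood, two mean adjusted estimators, the
    stage-wise median unbiased estimator, the Rao-Blackwell uniform minimum
    variance unbiased estimator, and their conditional-on-stopping-stage
    counterparts including a conditional weighted shrinkage estimator),
    exact conditional and marginal bias and residual mean square error
    evaluation, constructors for error-spending, power-family,
    O'Brien-Fleming and Simon-type designs, a Monte-Carlo trial simulator,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    optparse,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
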