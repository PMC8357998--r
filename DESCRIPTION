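Package: lcsdyn
Title: Simulation, Dynamics and Maximum-Likelihood Estimation of Latent
    Change Score Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the latent change score (LCS) family of longitudinal
    dynamic models: univariate dual, bivariate coupled, and stochastic
    variants with latent-level innovations.  Provides a seeded panel
    simulator with named illustrative scenarios, closed-form trajectory
    algebra (exponential solutions, asymptotes, continuous-/discrete-time
    conversion via the matrix exponential, eigenvalue-based shape
    classification), model-implied moments, full-information maximum
    likelihood with missing data, an independent Kalman-filter likelihood
    route, multi-start ML fitting with delta-method standard errors, and a
    parameter-recovery study harness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    MASS,
    Matrix,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
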