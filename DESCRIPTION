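Package: ropide
Title: Feedback-Rate Estimation for ROP1 Polarity Profiles in Pollen Tubes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Fits a mechanistic integro-differential model of steady-state
    ROP1 GTPase polarity on the pollen tube membrane. The stationary balance
    between superlinear positive feedback, linear negative feedback and
    lateral diffusion admits solutions of the form lambda * U_alpha(mu * x),
    where U_alpha solves a reference semilinear boundary-value problem.
    The package solves that reference problem, characterizes existence of
    positive solutions through a discriminant and a scalar root equation,
    estimates the shape parameters (lambda, mu) for a single tube by
    constrained nonlinear least squares and for a population of tubes by a
    constrained method of moments with noise-bias-corrected covariance, and
    converts shapes to positive and negative feedback rates with delta-method
    confidence intervals. Simulation generators for single tubes, tube
    populations and raw intensity matrices, plus iterative-PCA imputation
    and boundary normalization for preprocessing, allow the full pipeline
    to be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
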