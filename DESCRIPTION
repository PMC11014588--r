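Package: hebdcm
Title: Structurally Informed Effective Connectivity via Hierarchical
    Empirical Bayes Spectral DCM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of resting-state effective connectivity with
    structure-based priors. Fits spectral dynamic causal models to
    multivariate BOLD time series by variational Laplace on
    autoregressive cross-spectral features, pools subject posteriors in
    a parametric empirical Bayes random-effects model whose group-level
    prior variance is a linear function of normalized structural
    connectivity, scores candidate prior-variance transformations by
    analytic Bayesian model reduction over a hyperparameter grid,
    averages them by model evidence, and propagates the resulting
    empirical priors back down to subjects. Includes a synthetic-data
    generator for in-silico validation, a structurally masked
    multivariate autoregressive baseline, and parity and
    sign-classification metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    generics,
    tibble,
    dplyr,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
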