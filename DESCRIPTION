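Package: geoprev
Title: Bayesian Geostatistical Mapping of Child Underweight Prevalence
Version: 0.1.0
Authors@R: person("geoprev", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Model-based geostatistics for cluster-survey prevalence data.
    Fits a Bayesian binomial spatial regression with a logit link and a
    zero-mean Gaussian random field with Matern covariance, using MCMC
    (elliptical slice sampling for the latent field, adaptive random-walk
    Metropolis for regression and covariance parameters). Provides a
    synthetic DHS-like multi-wave cluster data generator with known ground
    truth, descriptive prevalence tables and trend statistics, covariate
    standardization and collinearity screening, kriging-style prediction
    surfaces on the probability scale, WAIC model comparison, and a
    reproducible command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
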