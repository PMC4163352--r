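Package: hankelcast
Title: Smoothing-Based One-Step-Ahead Forecasting of Surveillance Time
    Series
Version: 0.1.0
Authors@R:
    person("hankelcast", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Two-stage forecasting of univariate, regularly sampled
    health-outcome series such as weekly traffic-injury counts. Stage one
    smooths the series by a 3-point moving average or decomposes it into
    low- and high-frequency components via singular value decomposition
    of its Hankel trajectory matrix (HSVD). Stage two forecasts one step
    ahead from lagged smoothed values with a linear model with moving
    average errors (conditional sum of squares) or a single-hidden-layer
    autoregressive neural network trained by particle swarm optimization
    or resilient backpropagation. Includes RMSE/GCV/MAPE/relative-error
    metrics, residual autocorrelation whiteness diagnostics, Pitman's
    pairwise test of forecast-error variances, seeded synthetic-series
    generators, and a reproducible experiment pipeline with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
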