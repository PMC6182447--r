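Package: diffplm
Title: Difference-Based Estimation for Partially Linear Models with
    Dependent Errors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the parametric component of a partially linear model
    y = x'beta + f(t) + e by difference-based ordinary least squares
    (DOLS) and the nonparametric component f by a multiresolution
    wavelet reproducing-kernel smoother.  Supports dependent errors of
    the negatively superadditive dependent (NSD) type, including an
    exact sampler for NSD sequences obtained by conditioning iid
    draws on their sum, closed-form and heteroskedasticity/
    autocorrelation-robust plug-in variance estimators for the
    standardized estimators, and a Monte-Carlo study harness with
    empirical-distribution, quantile-quantile and Kolmogorov-Smirnov
    diagnostics of their asymptotic normality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    patchwork,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
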