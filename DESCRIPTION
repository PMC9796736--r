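Package: scoredif
Title: Score-Based Measurement Invariance Tests for 2PL and 3PL Item
    Response Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects differential item functioning (DIF) in binary item
    response data with score-based structural change tests.  Fits two- and
    three-parameter logistic models by marginal maximum likelihood or
    Bayesian maximum-a-posteriori estimation (single- or multiple-group,
    allowing ability impact between person groups), computes case-wise
    score contributions, and summarises their covariate-ordered cumulative
    sum process with double-maximum or unordered Lagrange multiplier
    statistics.  P-values come from a pooled-variance asymptotic route
    (Brownian bridge / chi-square references) or a simulation-based route
    that matches the end point of the observed process.  Includes a
    synthetic-data generator and a Monte Carlo study driver for size and
    power experiments.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
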