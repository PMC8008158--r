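Package: fpest
Title: Bayesian Estimation of Family Planning Indicators for a Single Population
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a Bayesian state-space model of contraceptive prevalence and
    unmet need for family planning to survey data from a single population of
    women (a country or subnational area, by union status). Systematic logistic
    growth trends with stationary AR(1) distortions describe total contraceptive
    use, the modern share of use, and unmet need; survey observations enter
    through a logit-scale likelihood with source-type biases and non-sampling
    error variances fixed from a supplied global-parameter fixture. Includes
    posterior summaries of derived indicators (prevalence, demand satisfied,
    user counts), all-women combination of union-status fits, aggregation
    across populations, MCMC convergence diagnostics, synthetic-data
    generation, plotting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
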