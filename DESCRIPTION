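Package: lagturn
Title: Lag-Regressed Species Turnover and Breakpoint Analysis for
    Community Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measures long-term change in short-term temporal species
    turnover from presence/absence community survey time series. Turnover
    is quantified as the regression slope of mean pairwise compositional
    similarity (Ochiai, Sorensen or Jaccard) against the time lag between
    surveys, after rarefying unequal sampling effort; before/since
    comparisons across candidate breakpoint years are summarised by the
    median change with a distribution-free exact confidence interval
    (equivalently a two-sided sign test). Includes a recursive
    delayed-response filter for annual climate series, a Lotka-Volterra
    community-assembly simulator of turnover under environmental shift
    and degradation with a polynomial response surface and AIC order
    selection, and a synthetic survey-data generator with closed-form
    expected similarity by lag for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
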