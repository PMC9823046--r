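Package: mrdoc2
Title: Bidirectional Mendelian Randomization with Twin Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural equation modelling of reciprocal causation between two
    phenotypes using monozygotic and dizygotic twin pairs and two polygenic
    scores as genetic instruments (the MR-DoC2 model). Provides the
    zygosity-specific model-implied moment structure, maximum-likelihood
    fitting to exact or sample moments, likelihood-ratio noncentrality and
    power calculations, numerical local-identification checks via the rank of
    the moment Jacobian, factorial power-study designs with
    variance-decomposition summaries, required-sample-size power curves, and
    parameterised bias experiments for pleiotropy and measurement-error
    assumption violations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
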