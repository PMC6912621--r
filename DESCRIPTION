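Package: drinkstates
Title: Latent Drinking-Pattern Analysis for Weekly Drinking Diaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives drinking outcomes from Daily Drinking Questionnaire
    style diaries (estimated blood alcohol concentration by the Widmark
    formula, weekly quantity and frequency, binge occasions, hazardous and
    excessive drinking status), discovers latent drinking states in 28-day
    diary sequences with a hurdle-emission hidden Markov model fitted by
    multi-restart Baum-Welch EM and selected by BIC, identifies and
    characterises a frequent-heavy drinking class (continual and itinerant
    members, group comparisons, arm-wise drinking-probability trends with
    cluster-robust standard errors), and simulates three-arm randomized
    trial cohorts with weekday-anchored drinking patterns, a nested add-on
    assignment, and wave-level missingness, so the whole pipeline is
    testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    sandwich,
    lmtest,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
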