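Package: propsi
Title: Adaptive Bayesian Assessment of Lower-Limb Position Sense
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the point of subjective equality (PSE) and
    uncertainty of static lower-limb position sense with an adaptive Bayesian
    two-alternative forced-choice procedure. Implements the Psi algorithm
    (joint grid posterior over a cumulative-Gaussian psychometric function,
    expected-entropy stimulus selection), the full 75-trial treadmill testing
    protocol (pseudorandomized movement directions, start-position sampling,
    preselected far/near stimuli, baseline correction), simulated observers
    that close the loop for testing, and a Bayesian test-retest agreement
    suite (Bland-Altman mean bias and bias-versus-true regression with
    HDI/ROPE summaries, limits of agreement, test-retest regression,
    ICC(2,1), and a hierarchical logistic model for movement-direction
    effects).
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
    purrr,
    Rcpp,
    readr,
    rjags,
    coda,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
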