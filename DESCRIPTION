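Package: truthfx
Title: Bayesian Modeling of the Repetition-Based Truth Effect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling how the plausibility of statements moderates
    the repetition-based truth effect. Implements the probit-link model of
    binary truth judgments with four variants of the fluency shift induced by
    repetition, a trial-level simulator with crossed participant and statement
    random effects, hierarchical Bayesian estimation via JAGS, marginal
    likelihoods by iterative bridge sampling with Bayes factors and posterior
    model probabilities, PSIS-LOO cross-validation, prior calibration that
    matches the implied average truth effect across model variants, and the
    quadratic-regression bootstrap test for the location of the peak truth
    effect together with its Monte Carlo power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
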