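Package: bayesnid
Title: Bayesian Sample Size Determination for Non-Inferiority Trials with
    Binary Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines sample size for two-arm non-inferiority trials with
    binary outcomes under three Bayesian approaches and a frequentist
    comparator. Predictive power averages the probability of a convincing
    Bayesian result over design priors for the arm event rates; the
    expected-posterior-probability approach targets the mean posterior
    probability of non-inferiority; the precision approach works from the
    closed-form credible-interval width for the risk difference and from
    acceptability (ACCEPT) curves. Conjugate Beta models are used for the
    event probabilities, with separate design and analysis priors, optional
    uniform priors on the non-inferiority margin, and seeded Monte Carlo
    engines with grid search for the smallest adequate sample size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
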