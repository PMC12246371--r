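Package: sretddm
Title: Hierarchical Drift-Diffusion and Mixed-Model Analysis of Self-Referential
    Encoding Task Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-alternative forced-choice data from the
    self-referential encoding task (SRET) collected under contrasting light
    conditions. Provides a synthetic-data generator mirroring a within-subject
    two-session design, an exact Wiener first-passage-time density with a
    bridge-corrected Euler-Maruyama simulator, hierarchical Bayesian estimation
    of drift-diffusion model variants by adaptive Metropolis-within-Gibbs with
    DIC model selection and split-chain R-hat diagnostics, posterior-overlap
    hypothesis tests, posterior-predictive reaction-time quantile checks, and
    random-intercept logistic regression of trial-level self-evaluation with
    BIC-based candidate comparison.
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
    lme4,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
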