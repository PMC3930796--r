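Package: hbchoice
Title: Hierarchical Bayesian Choice-Based Conjoint Analysis of Treatment
    Preferences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for discrete choice experiments (choice-based
    conjoint) on treatment preferences for chronic hepatitis B oral
    antivirals: blocked, level-balanced paired-choice designs; a synthetic
    respondent generator with multivariate-normal preference heterogeneity;
    a hierarchical Bayesian binary-logit model fitted by
    Metropolis-within-Gibbs MCMC with a compiled sampler; range-method
    relative importance, share-of-preference and one-attribute-at-a-time
    sensitivity post-estimation; and cost-sensitivity and treatment-attitude
    survey analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
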