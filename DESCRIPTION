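Package: socialstate
Title: Multistate Models of Male Reproductive Life-Histories in Cooperative Breeders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing discrete-time reproductive-role trajectories of
    males in cooperatively breeding groups, modelled on long-term banded
    mongoose field studies. Provides a synthetic cohort generator (groups,
    oestrus events, guard/sneaker/subordinate states, condition-dependent
    mortality, weight-skewed paternity), preprocessing into model-ready
    transition tables, Bayesian multistate transition and mortality models with
    crossed random effects fitted by adaptive Metropolis-within-Gibbs MCMC
    (compiled in C++), companion binomial paternity, Gaussian weight-change and
    zero-inflated negative binomial lifetime-reproductive-success models,
    split-Rhat convergence diagnostics, posterior-predictive probability
    curves, and a reproducible simulate-preprocess-fit-predict-report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
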