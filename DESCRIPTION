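Package: pebr
Title: Bayesian Model Reduction and Parametric Empirical Bayes for
    Hierarchical Group Studies
Version: 0.1.0
Authors@R:
    person("pebr", "maintainers", email = "pebr@example.org",
           role = c("aut", "cre"))
Description: Analytic Bayesian model reduction for nested Gaussian-prior
    models, variational Laplace inversion of nonlinear observation models,
    and parametric empirical Bayes for hierarchical (group) studies.
    Includes fixed- and random-effects Bayesian model comparison, Bayesian
    model and parameter averaging, exhaustive and greedy searches over
    second-level model spaces, Savage-Dickey predictive classification of
    held-out subjects with leave-one-out cross-validation, and a synthetic
    group-study generator for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
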