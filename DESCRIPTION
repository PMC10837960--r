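Package: alsmbma
Title: Model-Based Meta-Analysis of the ALS Placebo-Group Disease Course
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits nonlinear mixed-effects models to aggregate, arm-level
    placebo data from amyotrophic lateral sclerosis (ALS) trials: a
    parametric survival model (log-normal base hazard with
    proportional-hazards covariates) for overall survival digitized from
    Kaplan-Meier curves, and a sigmoid-Emax time-course model for the mean
    change from baseline in the revised ALS Functional Rating Scale
    (ALSFRS-R). Estimation uses a Laplace-approximated marginal likelihood
    with study-level random effects, forward/backward covariate selection,
    empirical-Bayes study estimates, and a nonparametric bootstrap.
    Includes goodness-of-fit and visual-predictive-check diagnostics,
    Monte-Carlo simulation of typical disease courses with uncertainty,
    random-effects subgroup meta-analysis, and application of the fitted
    models as external controls for single-arm trials and as priors for
    Bayesian borrowing in small placebo groups. A synthetic-corpus
    generator reproduces the statistical structure of the published trial
    corpus so the whole pipeline is testable without any data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    optparse,
    pracma
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
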