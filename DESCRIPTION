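Package: mbmasurv
Title: Model-Based Meta-Analysis of Aggregate Survival and Response Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for model-based meta-analysis (MBMA) of aggregate
    trial-level oncology data, built around digitized Kaplan-Meier curves.
    Fits a parametric log-normal survival model with proportional-hazards
    covariate effects and inter-trial random effects by maximising a
    Laplace-approximated marginal likelihood, and provides Monte-Carlo
    simulation of typical survival curves, two-step subgroup pooling,
    random-effects meta-analysis of proportions, trial-level surrogate
    endpoint regression, and model diagnostics (bootstrap, visual
    predictive checks, leave-one-out refits, goodness-of-fit residuals).
    Includes a synthetic-trial generator with known ground truth for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    metafor,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
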