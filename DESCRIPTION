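Package: helibelief
Title: Belief Updating Under Uncertainty in a Change-Point Predictive
    Inference Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of the "helicopter" change-point
    predictive inference task. Generates task schedules with abrupt
    change points and run-wise outcome noise, simulates behaving agents
    whose belief updates mix prediction-error-, change-point-probability-
    and uncertainty-driven components, computes normative change-point
    probability (CPP) and relative uncertainty (RU) trajectories with a
    reduced Bayesian observer (validated against a grid-based fully
    Bayesian filter), fits trial-wise belief-update regressions and
    group-level behavioural statistics, and builds first-level
    model-based fMRI designs with standardized, non-orthogonalized
    parametric modulators for GLM estimation on synthetic BOLD signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
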