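Package: criskit
Title: Competing-Risks Survival Analysis: Cause-Specific, Subdistribution and
    Augmented-Data Cox Models
Version: 0.1.0
Authors@R: person("criskit", "developers", role = c("aut", "cre"),
    email = "criskit@example.org")
Description: Tools for the analysis of right-censored time-to-event data with
    competing risks. Implements, from first principles, the three regression
    frameworks commonly compared in epidemiological competing-risks studies:
    Cox models on cause-specific hazards combined into covariate-conditional
    cumulative incidence functions, the Fine-Gray proportional
    subdistribution-hazards model with inverse-probability-of-censoring
    weighting, and the Lunn-McNeil augmented-data formulation (stratified and
    unstratified). Also provides the nonparametric Kaplan-Meier, naive
    1 - KM and Aalen-Johansen estimators, Gray's K-sample test for equality
    of cumulative incidence functions, the log-rank test, seeded cohort
    simulators (including a preset emulating a large diabetes registry with
    two highly unbalanced risks), and a comparison-report generator with a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
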