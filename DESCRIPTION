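Package: coldtrial
Title: Bayesian Adaptive Phase-II Monitoring and Paired Tumor-Microenvironment
    Statistics for Single-Arm Trials in Immunologically Cold Tumors
Version: 0.1.0
Authors@R:
    person("REGOMUNE", "Reanalysis Project", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the statistical machinery of a single-arm Bayesian
    adaptive phase-II trial in immunologically "cold" solid tumors: conjugate
    beta-binomial posterior monitoring of the objective response rate with
    futility and efficacy stopping rules (posterior-probability and
    predictive-probability interpretations), trial simulation and operating
    characteristics; Kaplan-Meier survival endpoints with medians, milestone
    rates and log(-log) confidence bands; duration of response and the
    growth-modulation index; and paired pre-/on-treatment multiplex
    immunofluorescence statistics on phenotyped cell maps (densities,
    radius-based colocalization, marker-positive fractions, exact paired
    Wilcoxon signed-rank tests). A synthetic-data module generates trial
    cohorts and paired cell maps with the assumed statistical structure so
    the whole pipeline runs without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
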