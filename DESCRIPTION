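Package: benrich
Title: Bayesian Adaptive Enrichment Designs for Two-Arm Trials with
    Categorical Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design, simulate and analyse Bayesian adaptive enrichment
    designs for two-arm randomized clinical trials with a binary outcome
    and a categorical (classifier) biomarker partitioning the population
    into K subsets.  Subset-level treatment effects are measured on the
    relative-risk scale under conjugate Beta-binomial models; sequential
    enrichment decisions combine a posterior influence (efficacy)
    condition with a treatment-by-subset interaction condition, the
    latter via either Millen's conditional ratio criterion (K = 2) or
    Bayesianized Gail-Simon qualitative and quantitative interaction
    statistics (K >= 2).  Includes a patient-level trial simulator with
    enrichment-aware accrual, grid-search calibration of decision
    thresholds controlling the design-level false positive rate, an
    operating-characteristics engine with prevalence and allocation
    sensitivity sweeps, and a real-trial mode replaying the sequential
    rules on a patient-level dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
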