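Package: trialcea
Title: Within-Trial Cost-Utility Analysis with EQ-5D-5L Utilities,
    Multiple Imputation and Bootstrapped Decision Outputs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for trial-based economic evaluation over a
    12-month horizon: scoring EQ-5D-5L responses against pluggable value-set
    (tariff) tables, quality-adjusted life years by trapezoidal area under
    the utility curve, resource-use and medication costing under health-system
    and societal perspectives, multiple imputation by chained equations with
    predictive mean matching, seemingly unrelated regression for adjusted
    incremental costs and effects, bias-corrected and accelerated bootstrap
    intervals, and decision outputs (incremental cost-effectiveness ratios
    with cost-effectiveness-plane quadrant semantics, net monetary benefit,
    and cost-effectiveness acceptability curves). Includes a calibrated
    synthetic two-arm trial generator with missing-at-random masking so the
    whole pipeline is testable without access to patient-level trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    boot,
    yaml,
    optparse,
    ggplot2
Config/testthat/edition: 3
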