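Package: carealert
Title: Threshold-Symptom Scoring and Two-Sample Proportion Inference for
    Caregiver e-Alert Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing serial caregiver-completed symptom check-ins
    from e-alert trials in advanced cancer. Provides a seeded synthetic cohort
    generator (weekly modified Edmonton Symptom Assessment Scale check-ins with
    carry-forward ratings, attrition, and arm-specific reporting bias),
    threshold-symptom scoring with improved/same/worsened transition labelling
    and bimonthly aggregation, two-sample binomial inference (pooled-variance Z
    test, unpooled Wald interval, Miettinen-Nurminen score interval, exact
    unconditional Chan-Zhang interval, Cohen's arcsine effect size h, and a
    two-group McNemar contrast for response-bias analysis), trapezoidal
    area-under-the-curve comparison of bimonthly proportion trajectories, and
    an end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
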