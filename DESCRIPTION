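Package: puadmin
Title: Positive-Unlabeled Learning for Case Ascertainment in Hospital
    Administrative Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for learning binary classifiers from positive and
    unlabeled (PU) hospital administrative case data, with sepsis coding as
    the motivating application. Provides a synthetic case-cost data
    generator with known class prior and label frequency under the SCAR and
    SAR labeling mechanisms, cohort filtering and undersampling, a two-step
    "spy" PU learner with a repeat-averaged reliable-negative threshold, an
    adaptive-resampling PU ensemble, PU-estimable evaluation metrics
    (recall, recall-at-k, precision-at-k) across five coding-strategy
    scenarios, and an external validity check that converts relabeling
    thresholds into population disease rates and rate ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
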