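Package: blcea
Title: Cost-Utility Modelling of Liquid-Biopsy Diagnosis for Burkitt Lymphoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-analytic cost-utility model comparing liquid-biopsy
    (circulating tumour DNA sequencing) against conventional histopathology
    for diagnosing Burkitt Lymphoma in children and young adults in a
    Tanzanian healthcare setting. Combines a diagnostic decision tree with a
    four-state Markov cohort model driven by a Weibull proportional-hazards
    survival function, computes discounted costs (Tanzanian Shillings) and
    disability-adjusted life years (DALYs), and reports incremental
    cost-effectiveness ratios against willingness-to-pay thresholds.
    Includes one-way (tornado) sensitivity analysis, probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves,
    scenario analyses, maximum-likelihood fitting of the survival model to
    right-censored patient records, and generators for synthetic patient
    records and a calibrated background life table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
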