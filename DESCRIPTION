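Package: recruitsim
Title: Randomized Recruitment Design, Power and Sample-Workflow Toolkit for
    Multicenter Observational Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and simulating multicenter observational
    studies built around concealment-preserving random-letter patient
    selection with adaptive enrollment-speed control. Includes a synthetic
    cohort generator for cystic-fibrosis-like populations, a rule-based
    pulmonary-exacerbation classifier with protocol sample-collection
    scheduling, bootstrap power and sample-size estimation for
    proportional-hazards and linear-regression biomarker endpoints,
    cohort-representativeness and seasonal-enrollment statistics, and
    biospecimen processing, labeling, split-batch shipping and quality
    control validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
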