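Package: ropscreen
Title: Validation Pipeline for an IGF1-Based Retinopathy of Prematurity Screening Rule
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pre-term infant cohorts with the joint structure of
    week-3 serum IGF1, neonatal sepsis and retinopathy of prematurity (ROP)
    outcome; fits the logistic ROP risk model behind probability-curve
    screening by iteratively reweighted least squares; encodes the two-tier
    screening decision rule (mandatory / high-risk / low-risk) and the AAP
    baseline; computes diagnostic accuracy (sensitivity, specificity, PPV,
    NPV) with exact Clopper-Pearson intervals from 2x2 screening-vs-outcome
    tables; and summarises week-3 to week-5 IGF1 percentage-increase
    trajectories by ROP grade with the accompanying group-comparison tests.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    readr,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
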