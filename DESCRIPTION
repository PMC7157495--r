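Package: rxaudit
Title: Audit of Written Versus Calculated Opioid Prescription Durations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a days-supply ("calculated duration") for outpatient
    opioid prescriptions from the dispensed tablet quantity, per-tablet
    strength, discrete dose and administration frequency, compares it with the
    duration the prescriber documented ("written duration"), and quantifies how
    often the dispensed supply outlasts the documented duration before and
    after an electronic-health-record intervention. Includes a PRN-aware
    frequency lexicon, a cohort inclusion/exclusion cascade with a full flow
    accounting, Wald and Wilson binomial confidence intervals, two-proportion
    chi-square, t-test and tie-aware Wilcoxon rank-sum comparisons, and a
    seeded synthetic prescription-extract generator so the whole pipeline is
    testable without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
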