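Package: mdcecon
Title: Economic Evaluation of a Multidisciplinary Lung Cancer Clinic
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Societal-perspective economic evaluation of a multidisciplinary
    lung cancer clinic (MDC) compared with a traditional sequential-referral
    model. Provides a seeded synthetic patient cohort generator calibrated to
    published cohort marginals, resource-utilization comparisons (visit means,
    two-sample tests, two-proportion tests), a base-case cost-savings model
    covering out-of-pocket, productivity (human-capital) and administrative
    savings, multi-way best/worst-case sensitivity analysis, and an
    incremental cost-effectiveness (ICER) and willingness-to-pay threshold
    analysis of invasive mediastinal staging by EBUS-TBNA. All monetary
    results are in 2019 Canadian dollars.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
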