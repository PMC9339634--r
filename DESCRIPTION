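Package: thyromine
Title: Association-Rule Discovery of Clinical Risk Factors from Categorical Patient Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Encodes clinical records as categorical transactions, mines frequent
    itemsets with independent from-scratch implementations of the Apriori and
    FP-Growth algorithms, generates class-targeted association rules under
    support/confidence thresholds, and keeps only the rules mutual to both
    algorithms as candidate risk factors. Ships discretization presets for two
    published thyroid-disease study designs (laboratory reference ranges, age
    bins, boolean comorbidities) and a synthetic transaction-database generator
    with planted patterns and known ground truth, so the whole pipeline is
    testable offline. The two miners are deliberately independent so their
    intersection acts as an integrity check on the mined rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    readr,
    readxl,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
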