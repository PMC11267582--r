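Package: faersignal
Title: Disproportionality Signal Detection and Time-to-Onset Analysis for
    Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for FAERS-style quarterly
    spontaneous-report tables: record cleaning (case deduplication,
    drug-synonym matching, primary-suspect filtering, preferred-term
    exclusions), construction of 2x2 drug-event contingency tables at the
    MedDRA PT and SOC levels, four signal-detection algorithms (reporting
    odds ratio, proportional reporting ratio with chi-squared, BCPNN
    information component, and gamma-Poisson shrinkage EBGM including the
    full DuMouchel empirical-Bayes fit), signal classification, Weibull
    time-to-onset modelling with goodness-of-fit and group comparisons, and
    descriptive reporting with sex-stratified signals. Ships a synthetic
    FAERS-like data generator with known ground truth so the whole pipeline
    is testable without the real database.
License: MIT + file LICENSE
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Encoding: UTF-8
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
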