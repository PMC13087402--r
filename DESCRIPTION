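Package: qsarpipe
Title: Small-Dataset QSAR/QSPR Modeling and Validation Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A workflow for descriptor-based structure-activity modeling on
    small compound panels: assay reduction (percent inhibition, IC50 from
    two-fold dilution series, pIC50 and MIC unit conversions), descriptor
    feature selection (stepwise multiple linear regression and
    correlation-based subset search with best-first expansion), multiple
    linear regression QSAR fitting, validation by leave-one-out and k-fold
    cross-validation, Y-randomization, leverage-based applicability-domain
    analysis (Williams plot), C4.5-style decision-tree QSPR classification
    with gain-ratio splits, and model-guided screening of designed candidate
    compounds. Includes a synthetic-data module generating descriptor tables
    with planted linear and rule-based structure for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
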