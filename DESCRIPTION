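Package: compmut
Title: Calling and Predicting Composite Mutations in Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify composite mutations (two or more independent
    driver-level genetic events in the same gene of the same tumor) from
    somatic mutation and gene-level copy-number cohorts, to characterize
    their co-mutation structure with per-stratum Fisher exact tests and a
    background-rate threshold, to quantify enrichment of co-mutations on
    the composite gene's chromosome with a randomization null
    ("chromosysmos"), and to predict composite-mutation status with a
    weighted two-model random-forest ensemble. Includes a synthetic tumor
    cohort generator with planted prevalence, co-mutation odds ratios and
    same-chromosome enrichment for parameter-recovery testing, and a
    single-call pipeline producing reproducible result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    randomForest,
    caret,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
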