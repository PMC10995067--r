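Package: agemeta
Title: Meta-Analysis and Meta-Regression of Age-Varying Genetic Effects
    from GWAS Summary Statistics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates main and age-varying genetic effects (SNP-by-age
    interactions) from per-study genome-wide association study summary
    statistics by random-effects meta-regression on study-level age
    moments.  Provides inverse-variance fixed-effect and REML
    random-effects meta-analysis, polynomial age meta-regression with
    centring and effect-by-age prediction, generalized-weight adjustment
    of standard errors for overlapping samples, an individual-level
    multi-study simulator with configurable between-study age overlap,
    and a Monte Carlo harness reporting bias, coverage and
    empirical/mean standard errors with Monte Carlo standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
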