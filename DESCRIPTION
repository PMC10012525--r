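Package: mahpselect
Title: Multi-Trait Genotype Selection with Stability Indices and the
    Modified Analytic Hierarchy Process
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multivariate genotype selection from replicated
    two-condition (normal versus stress) field trials. Estimates genetic
    parameters from randomized-complete-block ANOVA (broad-sense
    heritability on a family-mean basis, expected genetic advance, genetic
    correlations from mean cross-products), computes two trait-stability
    statistics (the Stability Index, an absolute stress-on-normal
    regression slope, and the Stability Index of Broad-sense Heritability,
    the stress/normal heritability ratio), weights traits by principal
    eigenvectors of consistency pairwise-comparison matrices (a
    measurement-driven variant of the analytic hierarchy process), scores
    families, and selects the top fraction. Includes a seeded simulator of
    balanced trials with known genetic architecture for estimator
    validation, and the summary tables of a 57-family tomato drought-stress
    case study as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
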