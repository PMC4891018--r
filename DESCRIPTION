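Package: mrscore
Title: Metabolite Risk Scores for One-Year Mortality from Censored
    Survival Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds and evaluates weighted metabolite risk scores for
    short-term mortality prediction from right-censored cohort data, as
    used in serum-metabolomics prognosis studies of pancreatic
    adenocarcinoma.  Provides Weibull proportional-hazards regression by
    maximum likelihood with AIC-guided stepwise selection and
    fractional-polynomial linearity checks, random-survival-forest
    variable screening with permutation importance, recursive
    partitioning and amalgamation (RECPAM) of risk classes, bootstrap
    stabilisation of score weights, censored-data concordance, and a
    seeded synthetic-cohort generator for end-to-end validation of the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
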