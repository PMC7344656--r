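Package: careaccess
Title: Small-Area Primary Care Access and Cardiometabolic Risk Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how geographic access to primary care relates
    to the small-area distribution of cardiometabolic risk factors. Computes
    two-step floating catchment area (2SFCA) access indices from area and
    provider point tables, dichotomises pathology test records into
    higher/lower risk outcomes, fits nested two-level random-intercept
    logistic regression models by maximum likelihood with adaptive
    Gauss-Hermite quadrature, and derives contextual-effect summaries
    (latent-variable intraclass correlation, median odds ratio, proportional
    change in variance, AIC and likelihood-ratio tests). A synthetic-region
    generator produces areas, providers, persons and outcomes with the
    statistical structure the analysis assumes, so the full pipeline is
    testable without restricted health data.
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
    rlang,
    ggplot2,
    jsonlite,
    readr,
    pracma,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
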