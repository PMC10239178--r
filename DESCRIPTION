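Package: eaamediate
Title: Mediation of Smoking Effects on Health Outcomes Through Epigenetic
    Age Acceleration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for causal mediation analysis of
    smoking exposures (status, pack-years, years since cessation) acting on
    diabetes-related and spirometric outcomes through DNA-methylation
    biomarkers of aging (epigenetic age acceleration, DNAm-predicted
    pack-years and PAI-1 levels, DunedinPACE). Implements paired
    mediator-model/outcome-model ordinary least squares fits with dummy-coded
    smoking status, product-of-coefficients indirect effects with
    nonparametric case-resampling bootstrap confidence intervals, a
    Bonferroni exposure-mediator screen, Benjamini-Hochberg FDR control over
    the full exposure x mediator x outcome grid, Tukey 3xIQR extreme-outlier
    exclusion, log/z-score outcome transforms, and a seeded synthetic-cohort
    generator with closed-form ground-truth indirect effects for
    parameter-recovery testing.
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
    car,
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
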