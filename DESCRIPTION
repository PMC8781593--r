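Package: ariburden
Title: Acute Respiratory Infection Episodes and Symptom Burden from Daily
    Diaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing daily symptom diaries from infant birth
    cohorts. Segments diaries into acute respiratory infection (ARI)
    episodes under an A/B-symptom case definition (any A-symptom, or two
    distinct B-symptoms, starts an episode; three consecutive symptom-free
    days end it), computes per-child and cohort symptom-day burden,
    prevalence and seasonality curves, Welch mean-difference comparisons
    across covariate strata, and crude and adjusted Poisson rate-ratio
    models of two-year episode counts. Includes a seeded synthetic-cohort
    generator (covariates, two-year daily diaries, latent ground-truth
    episodes) with age- and season-dependent onset hazards so that every
    pipeline stage is testable without access to the original study data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
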