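Package: dietlife
Title: Composite Diet and Lifestyle Quality Indices with Covariate-Adjusted
    Outcome Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Scores composite diet and lifestyle quality indices from
    food-frequency-derived intakes (Mediterranean diet score with
    cohort-median cut-points, a six-component modified WCRF/AICR
    cancer-prevention adherence score, and the nine-component Extended
    Healthy Lifestyle Index), derives clinical and patient-reported
    outcomes (HOMA-IR, anthropometric indices, FACIT quality-of-life and
    HADS anxiety/depression scores with proration rules), applies an
    energy-plausibility exclusion cascade, fits z-standardized
    covariate-adjusted association models with Bonferroni evidence tiers,
    and quantifies between-index agreement with Spearman correlation and
    weighted kappa. Includes a seeded synthetic-cohort generator with
    plantable exposure-outcome effects so the whole pipeline is testable
    without participant data.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
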