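Package: achondro
Title: Growth Reference Curves and Registry Summaries for Achondroplasia
    Natural History Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for working with multicenter achondroplasia natural-history
    registries: a typed registry container with flat-file readers and writers,
    a seeded synthetic-cohort generator that emulates the statistical structure
    of such registries (demographics by birth decade, heteroscedastic
    sex-specific growth trajectories, surgical events, polysomnography
    outcomes, imaging catalogues, and injectable measurement errors), the
    published exclusion rules and a documented anthropometry QC layer,
    sex-specific empirical percentile curves built from age-windowed order
    statistics and smoothed with penalized splines, height-velocity and
    growth-milestone estimation, comparison against external (LMS or direct
    percentile) reference curves, and summary-table engines mirroring the
    standard natural-history report layout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
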