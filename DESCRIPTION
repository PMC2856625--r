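Package: serochip
Title: Allergen Microarray IgE Quantification and Reproducibility Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies allergen-specific IgE from two-channel protein
    microarray scans. Reads GenePix-Results-style spot tables, corrects
    per-allergen autofluorescence with linear models fitted on mock
    (buffer-only) arrays, calibrates allergen-specific detection thresholds
    at an empirical percentile of the corrected mock distribution so the
    held-out false-positive rate is controlled, and aggregates replicate
    spots with a robust Tukey biweight mean into a sera-by-allergens matrix
    of microarray units. Includes reproducibility statistics (coefficient of
    variation by replication level, ANOVA variance partitioning, pairwise
    replicate regression), ELISA concordance tables, hierarchical clustering
    of IgE profiles with bootstrap (BP) and multiscale-bootstrap (AU)
    support values, and a fully parameterized synthetic-study generator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
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
    utils,
    withr
Suggests:
    ape,
    testthat (>= 3.0.0),
    yaml
Encoding: UTF-8
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
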