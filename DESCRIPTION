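Package: microdiet
Title: Multi-Cohort Diet-Pattern Microbiome Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for cross-cohort analysis of habitual diet
    patterns (omnivore, vegetarian, vegan) and the gut microbiome:
    healthful plant-based diet index (hPDI) scoring from food-frequency
    questionnaires, alpha/beta diversity with sequential-term PERMANOVA,
    covariate-adjusted standardized mean differences of arcsine-square-root
    transformed relative abundances pooled by DerSimonian-Laird
    random-effects meta-analysis, Fisher-Z pooling of partial Spearman
    correlations, random-forest validation with cross-validation, LODO and
    cross-LODO schemes, and food-to-gut species overlap calling. A synthetic
    multi-cohort generator with planted effects provides a ground-truth test
    surface so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    vegan,
    ranger,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    picante,
    optparse,
    withr
Config/testthat/edition: 3
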