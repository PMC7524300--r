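Package: milkphen
Title: Infant Gut Microbiota Profiling Across Milk-Feeding Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing infant gut microbiota across milk-consumption
    groups (breastfed, pumped human milk, traditional formula, and
    lactose-reduced formula with added corn syrup solids). Implements
    Community Phenotype Index (CPI) profiling of predicted metabolic
    capabilities from 16S-derived taxon abundances, robust Aitchison
    ordination by iterative low-rank matrix completion with perMANOVA,
    covariate-adjusted per-feature group comparison (full-versus-reduced
    ANOVA, Tukey-Kramer post hoc, permutation-based false discovery rate
    confidence intervals), and a synthetic-cohort generator with
    Dirichlet-multinomial count noise for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    stats,
    utils,
    generics,
    jsonlite
Suggests:
    vegan,
    biomformat,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
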