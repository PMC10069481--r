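Package: hostpref
Title: Mosquito Host-Preference Assays and Skin-Odor Metabolomics Consensus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-choice olfactometer host-preference
    assays and untargeted GC/QTOF-MS skin-odor feature tables. Scores
    olfactometer trials with explicit inclusion criteria, runs rank-based
    pairwise preference statistics with Bonferroni correction and
    nonparametric effect sizes, aggregates round-robin competitions into
    per-subject attraction scores, and implements a feature-consensus
    metabolomics workflow (fuzzy mass/retention-time deduplication,
    prevalence and coefficient-of-variation quality filters, half-minimum
    imputation, per-experiment differential abundance with
    Benjamini-Hochberg control, cross-experiment consensus calling, and
    accurate-mass CHNO formula prediction). Includes synthetic-data
    generators with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
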