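Package: phasewave
Title: Growth-Phase Resolved Analysis of Batch-Culture Expression, Morphology
    and Metabolite Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for systems analysis of microbial batch growth curves:
    partition of OD600 trajectories into early, exponential, transition and
    stationary phases; per-gene likelihood-ratio (lambda) significance of
    two-colour expression ratios under an additive plus multiplicative error
    model, with a consecutive-condition persistence filter and threshold sweep
    tables; K-means discovery and rule-based classification of temporal
    expression archetypes; permutation t-tests with false-significant-
    proportion control for strain comparison; hypergeometric replicon
    enrichment; two-component Gaussian mixture modelling of single-cell
    circularity across growth; and metabolite phase-profile filtering and
    transcript concordance scoring. Includes seeded synthetic-data generators
    with recoverable ground truth for every data type, and a pipeline driver
    that runs all stages end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
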