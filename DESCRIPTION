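Package: galliso
Title: Hybrid Compatibility, Haldane's Rule and Domestication in Landfowl
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of postzygotic reproductive isolation among
    hybridizing landfowl (Galliformes) species pairs. Fits logistic time
    courses of Haldane's Rule and complete reproductive isolation with
    50%-probability crossing points, builds trait-difference predictors
    (habitat mismatch, clutch-size difference, PCA-reduced morphological
    differences) of an ordinal isolation score with stepwise AIC selection,
    derives a per-species reproductive-isolation index from regression
    residuals, computes a corpus-based domestication index by longest-match
    species-name counting, tests the domestication-compatibility association
    with phylogenetic generalized least squares and phylogenetic-signal
    statistics, and runs permutation-based publication-bias diagnostics. A
    synthetic-data generator (Yule trees, Brownian traits, an ordered-logit
    cross simulator and planted-occurrence text corpora) makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    nlme,
    optparse,
    phytools,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
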