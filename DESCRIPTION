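Package: amylometa
Title: Logistic Meta-Prediction of Amyloidogenic Hot Spots in Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines complementary hexapeptide window scorers (residue scales and
    position-specific matrices) into a logistic-regression meta-predictor of amyloid
    aggregation hot spots. Provides maximum-likelihood fitting with stepwise BIC
    predictor selection and cross-validated scores; per-residue amyloidogenicity
    profiles with hot-spot calling and the AGGRESCAN-style Total Area and Normalized
    Hot Spot Area statistics; mutation-effect deltas between wild-type and variant
    sequences; a predictor-evaluation toolkit (ROC, AUC, partial AUC, DeLong
    comparison of correlated AUCs, stratified bootstrap confidence intervals,
    threshold selection, per-residue confusion counts); and seeded synthetic-data
    generators for labelled hexapeptide sets, logistic feature matrices and proteins
    with planted hot spots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
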