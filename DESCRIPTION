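Package: posmna
Title: Pairwise Drug-Drug Interaction Prediction from PoSMNA Substructure
    Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts metabolic drug-drug interactions mediated by the seven
    major cytochrome P450 isoforms (CYP1A2, CYP2B6, CYP2C19, CYP2C8, CYP2C9,
    CYP2D6, CYP3A4) for unordered pairs of small molecules. Molecules are
    described by canonical Multilevel Neighborhoods of Atoms (MNA) substructure
    strings; a pair of substances is described by the direct product of the two
    molecules' MNA/2 sets (PoSMNA descriptors). A naive Bayes activity-spectrum
    model scores each pair against each isoform and calibrates the scores into
    Pa ("to be active") and Pi ("to be inactive") probabilities whose
    difference dP ranks the isoforms. Model quality is estimated by analytic
    leave-one-out cross-validation scored with IAP, the tie-adjusted
    probability that a random interacting pair outscores a random
    non-interacting one (numerically the AUC ROC). Includes readers and
    writers for SMILES, SDF (V2000), pair tables and versioned model JSON, a
    seeded synthetic-data generator with planted, recoverable
    structure-activity rules, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ChemmineOB,
    jsonlite,
    withr,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    igraph,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
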