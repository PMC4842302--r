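Package: multisea
Title: Similarity Ensemble Approach Target Prediction with Multi-Fingerprint Voting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ligand-based target prediction with the chemical Similarity
    Ensemble Approach (SEA). Activity tables are curated into per-target
    ligand sets, molecules are encoded with pluggable 2D fingerprints
    (Morgan-style circular, atom pair, topological torsion, MACCS keys,
    2D pharmacophore, SHED descriptors), and set-set similarity raw scores
    are calibrated against a random background whose Z-scores follow an
    extreme value distribution, yielding P-values for ligand-target and
    target-target associations. Several single-fingerprint models can be
    combined through a k-vote election scheme, and predictions are scored
    with confusion-matrix metrics including F-beta measures. A synthetic
    fingerprint universe generator with planted target families supports
    fully self-contained testing and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
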