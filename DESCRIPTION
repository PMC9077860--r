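Package: etaqsar
Title: Extended Topochemical Atom Descriptors and Validated PLS QSAR Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes Extended Topochemical Atom (ETA) descriptors from
    molecular graphs parsed from SMILES or SDF, and builds quantitative
    structure-activity relationship (QSAR) models on top of them: descriptor
    pretreatment, k-medoids based train/test division, genetic-algorithm
    descriptor selection under double cross-validation, NIPALS partial least
    squares regression, and a validation suite covering internal and external
    predictivity (Q2 leave-one-out, Q2F1/Q2F2), Y-randomization, variable
    importance, Hotelling T2 and DModX applicability-domain diagnostics. A
    synthetic-data generator produces terpene- and phenylpropanoid-like
    molecule sets with linearly structured activities so that every stage of
    the pipeline can be exercised and tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
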