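Package: adrsim
Title: Similarity-Based Prediction of Drug Side Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts adverse drug reactions from seven similarity measures
    over drug and side-effect properties: drug-drug interaction triples,
    GO-term overlap of network component genes between drug targets,
    SNP-regulated gene sets of indicated diseases, indications, targets,
    chemical fingerprints (Tanimoto), and a three-level side-effect
    anatomical hierarchy. Drug-side-effect pairs receive leakage-aware
    maximum-similarity feature values computed against training positives
    only, are evaluated by repeated hold-out resampling with balanced
    negative sets under four base classifiers plus a stacking ensemble,
    and candidate predictions are validated by Fisher's exact enrichment
    against pharmacovigilance association lists. A synthetic-data
    generator emulates the full input universe for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    ranger,
    e1071,
    xgboost,
    glmnet,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ChemmineR,
    ChemmineOB,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
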