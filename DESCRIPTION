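Package: offtarget
Title: Consensus Off-Target Prediction and Exposure-Aware Drug Repurposing Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale computational drug-repurposing toolkit. Profiles small
    molecules with 2D pharmacophore descriptors (hashed path fingerprints,
    pharmacophoric fragments, feature-pair distance distributions and their
    Shannon entropies), predicts protein targets with six ligand-centric
    methods (active-subgraph signatures, per-target QSAR scorers, descriptor
    similarity, set-wise ligand similarity with extreme-value statistics, a
    three-classifier machine-learning consensus, and cross-pharmacology
    indices), aggregates them into a normalized pseudo-score, refines
    predictions with cross-species tissue-expression atlases, and triages
    repurposing candidates against clinical exposure (pCmax versus pIC50).
    Includes a seeded synthetic-fixture generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    Matrix,
    glmnet,
    randomForest,
    e1071,
    nnet,
    igraph,
    jsonlite,
    yaml,
    withr,
    pheatmap,
    stats,
    utils
Suggests:
    ChemmineR,
    ChemmineOB,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
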