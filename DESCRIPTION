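Package: complexforge
Title: Confidence Scoring, Restraint Validation and Greedy Assembly of
    Predicted Protein Complex Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-prediction analysis of pairwise protein complex models
    carrying per-residue plDDT confidence in the B-factor field. Detects
    interface residues, computes the pDockQ interface confidence score,
    classifies direct versus indirect chain contacts, validates models
    against lysine-lysine crosslinking mass spectrometry distance
    restraints, maps mutation and phosphosite tables onto interfaces with
    enrichment statistics, clusters co-regulated interface phosphosites
    from condition fold-change panels, and greedily assembles higher-order
    complexes from ranked dimer models using TM-score shared-chain gating
    and Calpha clash rejection. Includes a synthetic-fixture generator
    producing multi-chain complexes with known ground-truth transforms,
    planted crosslinks and planted co-regulation clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
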