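Package: smirl
Title: Two-Stage SMILES Language Modeling and Reinforcement-Learning
    Molecule Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De novo molecule generation by a two-stage procedure: a
    decoder-only (GPT-style) transformer language model is trained on SMILES
    strings by next-token prediction, then fine-tuned with REINFORCE policy
    gradients to maximise a terminal molecular-property reward such as
    drug-likeness (QED), predicted potency (pIC50), or an external
    predictor's output probability. Includes character-level and byte-pair
    (BPE) SMILES tokenizers, autoregressive sampling, validity-gated reward
    functions, the standard generative-chemistry evaluation metrics
    (validity, novelty, diversity, QED and synthetic-accessibility
    statistics), a deterministic synthetic-corpus generator for offline
    training and testing, and a command-line workbench. Molecular parsing
    and property scoring are delegated to RDKit through a bundled batch
    bridge.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
SystemRequirements: Python (>= 3.8) with rdkit, discovered on PATH as
    'python'; used for SMILES validity, canonicalisation, QED and SAS.
Config/testthat/edition: 3
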