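Package: hmsvmPPI
Title: Protein-Protein Binding Site Prediction with Hidden Markov Support
    Vector Machines and Order-Profile Propensities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-residue prediction of protein-protein interface residues
    from sequence-derived evidence. Combines evolutionary frequency
    profiles (PSI-BLAST PSSMs), relative solvent accessibility and a
    learned order-profile propensity into sliding-window features for a
    linear-chain max-margin sequence labeler (hidden Markov support
    vector machine) trained by structured perceptron or one-slack
    cutting-plane optimisation and decoded by Viterbi. Includes readers
    for FASTA, PSI-BLAST ASCII PSSM and DSSP-derived accessibility
    tables, a synthetic-data generator emulating clustered interface
    segments, a chain-level cross-validation harness with
    sensitivity/specificity/F1/MCC/AUC reporting, and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
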