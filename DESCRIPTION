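Package: deepfragk
Title: Two-Stage Fragment-Based Protein Fold Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fragment-based protein fold recognition in two stages. Stage one
    scores every sliding-window fragment (4-20 residues) of a protein sequence
    against a library of structural fragment classes with a multimodal deep
    belief network over three feature groups (sequence composition,
    physicochemical properties, PSSM-derived evolutionary features); stage two
    aggregates the per-window class distributions into a fixed-length fragment
    vector and classifies it into a fold with a one-dimensional convolutional
    network. Includes readers and writers for FASTA and PSI-BLAST ASCII PSSM
    profiles, a synthetic fragment-library and fold-dataset generator for
    desk-scale training and validation, and stratified cross-validation
    utilities with per-class precision and recall reports.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
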