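Package: sulfenR
Title: Prediction of Protein S-Sulphenylation Sites from Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for predicting cysteine S-sulphenylation (Cys-SOH)
    sites from protein sequence. Extracts 21-residue cysteine-centred
    motifs from FASTA, computes nine sequence and structural feature
    encodings (amino-acid composition, k-spaced amino-acid pairs,
    BLOSUM62, PSSM, AAindex, one-hot, predicted disorder, secondary
    structure and surface accessibility), ranks features by minimum
    redundancy maximum relevance with MDL discretization, selects a
    subset by forward incremental search, and trains a two-stage stacked
    ensemble of random forests and support vector machines combined by a
    small feed-forward neural network. Includes parsers for PSI-BLAST,
    DISOPRED, PSIPRED and NetSurfP output, a deterministic mock
    annotation provider, a synthetic motif generator for end-to-end
    testing, stratified cross-validation and standard evaluation
    metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    seqinr,
    ranger,
    e1071,
    nnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    withr
Config/testthat/edition: 3
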