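Package: ProtSubLoc
Title: Two-Layer Multi-Label Prediction of Human Protein Subcellular
    Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the subcellular localization of human proteins across
    six compartments (cell membrane, cytoplasm, ER/Golgi, mitochondrion,
    nucleus, extracellular), including multiplex proteins that reside in more
    than one compartment. Sequences are encoded with region-wise amino acid
    composition, a weighted sign amino-acid-index transform over 100
    physicochemical scales, parallel-correlation pseudo amino acid
    composition, optional surface-accessibility aggregates, a sequence
    similarity profile, and Gene Ontology term features selected by a
    mutual-information mRMR procedure. A first layer of per-location binary
    support vector machines trained on disjoint negative partitions feeds a
    second layer combining a genetic-algorithm-trained neural network and
    strict-majority voting into a predicted location set. Evaluation uses the
    absolute true success rate (exact set match) with per-location and
    singleplex/multiplex breakdowns and a nested five-fold cross-validation
    that keeps second-layer training rows out-of-fold. A synthetic proteome
    generator makes every stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    e1071,
    seqinr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
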