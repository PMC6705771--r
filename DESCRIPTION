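Package: fusemine
Title: Mining Fusion-Protein Mentions and Their Interactions from Biomedical Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Recognizes gene-fusion mentions (e.g. BCR-ABL, bcr/abl, BCR:ABL1)
    across the surface dialects used in biomedical abstracts, normalizes them to
    canonical identifiers, extracts sentence-level statements linking fusions to
    interaction partners and diseases via an action-verb lexicon, and classifies
    candidate documents with an N-gram bag-of-words multinomial Naive Bayes
    model. Includes a Porter2 (Snowball English) stemmer, a TF-IDF-style
    frequency-score threshold for vocabulary selection, a deterministic
    synthetic-corpus generator with gold annotations, MEDLINE/PubMed-XML
    readers, GraphML evidence-network export, and a full evaluation harness
    (precision/recall/F-score, stratified cross-validation, ROC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    igraph,
    Matrix,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
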