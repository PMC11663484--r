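Package: metannot
Title: Interpretable Annotation of Biomedical Metadata to Ontology Terms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates unstructured biomedical sample and study metadata
    (e.g. GEO-style free-text descriptions) to controlled disease and
    tissue/cell-type ontology terms. Text is normalized into token streams,
    converted to TF-IDF vectors over word, phrase, or cluster entities, and
    classified with one elastic-net logistic regression model per ontology
    term. At prediction time, words unseen during training are projected
    onto their most embedding-similar training feature so that any
    biomedical text can be scored, with a full trace explaining each
    mapping. Includes OBO ontology parsing with information-content
    computation, prior-normalized auPRC evaluation, pairwise term
    discrimination auROC, term-name ablation, shuffle-normalized
    accuracy/F1, and a synthetic-corpus generator for fully offline
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    glmnet,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
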