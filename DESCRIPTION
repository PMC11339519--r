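Package: ontolord
Title: Ontology-Grounded Concept Embeddings via Contrastive Learning,
    Self-Distillation and Weight Averaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An encoder-agnostic pipeline for learning biomedical concept and
    sentence representations from an ontology: contrastive training of concept
    names against their definitions and verbalized knowledge-graph relations
    with in-batch negatives (InfoNCE), supervised self-distillation of a fresh
    base encoder onto PCA-reduced averaged concept embeddings through a linear
    projection head, uniform weight averaging ("model soup") of seed-varied
    students, and cross-lingual distillation of the resulting monolingual
    teacher into a multilingual student over a mined parallel concept-name
    corpus. Ships readers for pipe-delimited UMLS-style concept, definition
    and relation tables, an evaluation harness for semantic textual similarity
    (Pearson), concept relatedness (Spearman) and dense entity linking (Top-k
    accuracy with semantic-type filtering), a trainable character n-gram
    reference encoder so every phase runs on one CPU, and a deterministic
    synthetic-ontology generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
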