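Package: ragre
Title: Retrieval-Augmented and Chain-of-Thought Prompting for Biomedical
    Document-Level Relation Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for zero-shot biomedical document-level relation
    extraction with large language models. Relation decisions between typed
    entity pairs (chemical-disease, gene-disease, drug-adverse event) are
    reframed as natural-language questions, grounded with an external
    knowledge corpus built from literature abstracts by explicit
    co-occurrence selection rules and multi-strategy text chunking
    (sentence, sliding window, paragraph), retrieved by sentence-embedding
    cosine similarity, and answered through chain-of-thought prompts with a
    constrained answer protocol. Pluggable encoder and generator backends,
    deterministic offline mocks, a synthetic fixture generator, and a
    precision/recall/F1 evaluation harness make every stage of the pipeline
    testable without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
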