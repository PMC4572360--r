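Package: goqa
Title: Deep Question Answering over Gene Ontology Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for answering natural-language questions about protein
    function with Gene Ontology (GO) concepts. Implements an OBO ontology
    parser and writer, GAF annotation and abstract-corpus readers, an
    inverted-index Okapi BM25 retrieval engine, two interchangeable GO
    classifiers (a dictionary/vector-space classifier with literal pattern
    matching, and a k-nearest-neighbour classifier voting over a curated
    annotation knowledge base), a question-answering pipeline that aggregates
    per-abstract predictions by citation counting, ranked-retrieval evaluation
    metrics (top precision and recall at rank, with a paired sign-flip
    randomization test), and a seeded synthetic-data generator for offline
    benchmarking of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    stringi,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
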