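Package: sparqlgen
Title: Schema-Guided SPARQL Query Generation and Execution-Based Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Answers natural-language questions over biological RDF databases
    by splitting the task in two: a language model extracts schema variables
    and parameter (variable, value) bindings from the question, and a
    deterministic query builder turns them into a syntactically valid SPARQL
    SELECT query by traversing a curated YAML schema tree. Includes an
    execution-based scoring metric for knowledge-graph question answering
    (per-row Jaccard similarity combined through maximum-weight bipartite
    matching, normalised by the larger table), a restricted Turtle reader and
    in-process evaluator for the emitted query dialect, synthetic schema and
    graph generators, and a benchmark campaign runner with a pluggable,
    offline-testable language-model client.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    clue,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    curl,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
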