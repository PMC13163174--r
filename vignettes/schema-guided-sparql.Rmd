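---
title: "Schema-guided SPARQL generation and execution-based scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Schema-guided SPARQL generation and execution-based scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparqlgen)
```

## The problem and the split

Life-science knowledge graphs (protein, reaction, and expression databases
published as RDF) are queried with SPARQL, whose difficulty is dominated by
one thing: knowing the property paths of the database's RDF model. A language
model asked to write SPARQL end-to-end must learn both the schema and the
syntax, and tends to hallucinate structure. This package splits the task:

1. **Extraction** (language model): given a curated listing of schema
   variables, decide which variables the question wants retrieved and which
   (variable, value) conditions constrain the search.
2. **Query construction** (deterministic code): traverse the schema tree from
   each subject-root to the selected variables and emit the triple patterns,
   a `SELECT DISTINCT` clause, and `VALUES` blocks for the conditions.

The model's output is a closed vocabulary (schema variable names) plus values
it is told to copy verbatim from the question, so the generated query is
syntactically valid by construction and every model-induced error is
attributable to the extraction step.

## The schema model

A schema is a forest: each database entry class is a subject-root carrying
one or more `rdf:type`s, and attributes are child nodes reached through
predicates. Nodes have human-readable variable names (unique, identifier
syntax, so they can be emitted as SPARQL variables unchanged), an example
value, and optionally a curated explanation.

The YAML dialect accepted by `parse_schema()` is a deliberate, documented
subset of the upstream schema-repository format rather than a guess at its
full grammar: top-level `name` / `prefixes` / `model`, subject blocks headed
`"<VariableName> <example>"`, `a:` entries for types, predicate entries for
children, and nested lists for subtrees. Anything outside the subset is
rejected with a precise error. Constructs we do not attempt (cardinality
annotations, language tags, endpoint files) are out of scope.

Two open points the upstream format leaves unstated were decided as follows:

* **Connector classification.** A non-root node with children and no explicit
  `selectable: true` flag is a connector: it links property paths but is
  excluded from the variable listing shown to the extraction model, since the
  builder resolves it internally. The flag exists because some internal nodes
  are genuinely meaningful to users.
* **Example values are opaque.** They document the variable and are shown to
  the model, but never participate in query generation and are never
  validated against the prefix map (real schemas mix prefixed names and raw
  identifiers).

Multiple subject-roots in one document are accepted, and `merge_schemas()`
concatenates disjoint schemas into one forest for cross-database questions.
Document order fixes node, edge and root precedence everywhere, which is what
makes parsing, building and rendering deterministic.

## Query construction

`build_query()` takes a request of `variables` (items to retrieve) and
`parameters` ((variable, value) pairs). Choices that were genuinely open:

* **`SELECT DISTINCT` always.** Result tables are compared as sets of rows;
  without `DISTINCT` the score would depend on store internals.
* **Constraints use `VALUES`, never `FILTER`** — the generated dialect stays
  a pure basic graph pattern plus explicit bindings, easy to audit and easy
  to post-edit. Multiple values for one variable share a single `VALUES`
  block (disjunction).
* **Parameter variables are not auto-selected.** Retrieving them is the
  user's call; the worked citation example selects only the citation
  variable.
* **Value typing rule.** `prefix:local` with a declared prefix → prefixed
  name; a double-quoted value → literal verbatim; anything else → plain
  literal. This accommodates conditions that are entity IRIs as well as
  free-text terms.
* **Cross-database requests** against a merged forest emit each root's
  pattern group into one WHERE block with no implicit join (a cross
  product). Joining entities across databases, when wanted, is expressed by
  binding the same value to variables of both schemas; inventing silent join
  semantics seemed worse than none.
* **Not generated:** aggregation (`COUNT`/`GROUP BY`), `ASK`, `OPTIONAL`,
  `UNION`, `REGEX`. The builder's output is deliberately limited to simple
  searches; post-editing generated queries into such forms is a documented
  hook left to callers.

Rendering is fixed-layout and byte-deterministic; prefix declarations are
restricted to prefixes actually used and sorted by label.

## Extraction

The prompt walks the model through four steps — extracting user requests,
converting requests to variables, extracting user-specified conditions,
converting conditions to parameters — and demands a final fenced `json`
block with keys `variables` and `parameters`. JSON was chosen for the answer
contract because parameter values must round-trip byte-exactly (YAML scalar
typing would rewrite values like `1e5`). The shipped template follows the
four steps but is this package's own wording, overridable per call.

Three presentation modes control what the model sees: `VwE` (names, examples
and explanations — the default), `VwoE` (names and examples only), and
`VinS` (the raw schema document). All three produce well-formed prompts;
connector names never appear in listing-based prompts.

Validation is strict: an unknown variable name is a hard error naming the
offenders — no fuzzy matching, no silent dropping — so extraction errors
surface instead of leaking into queries. The **strict-copy guard** warns (but
does not block) when a parameter value is not a verbatim, case-sensitive
substring of the question; the canonical failure it catches is operator
drift inside copied reaction equations (`=` rewritten to `=>`). It checks
the question only, never database content, and it is advisory because
legitimate normalisation can trip it. Entity recognition/normalisation
(mapping "mouse" to a taxonomy ID) is a pre-processing concern outside this
package; the extraction contract assumes question text already matches
database terms.

The client contract (`llm_client()`) is a function from prompt bundle to
completion string plus metadata; deterministic settings (temperature 0) are
the recorded default, and the bundled `mock_llm_client()` is a pure function
of the prompt, which is what makes the whole pipeline reproducible in tests
and campaigns.

## Execution

No R-side RDF stack is assumed: the package carries a restricted Turtle
reader/writer and an in-process evaluator scoped to exactly the dialect the
builder emits (basic graph patterns, `VALUES`, `SELECT DISTINCT`). The
evaluator is a nested-loop join — transparent and adequate at fixture scale
(hundreds of triples, a handful of patterns). Remote execution speaks the
SPARQL Protocol with an injectable transport and parses the standard JSON
and XML result serializations identically. Distinct condition classes
separate transport failures, HTTP errors, and malformed result documents;
there are no retries by default (reproducibility over robustness), and a
configurable row cap warns when an endpoint may have truncated.

Cell normalisation, shared by both executors: IRIs compare as full IRI
strings; literals by lexical form with datatype and language tag stripped;
comparisons are case-sensitive; blank nodes are renamed to a stable
per-table sequence (`_:b1`, `_:b2`, …) in first-seen order so equal
structures compare equal across runs.

## The metric

Rows are value **sets**: duplicates inside a row collapse and column identity
is ignored, because row similarity is defined as the Jaccard coefficient of
two value sets. The table score matches rows one-to-one by maximum total
similarity and normalises by `max(N_g, N_q)`, penalising unmatched rows.
Conventions the formula leaves open, fixed as package policy: two empty
tables score 1.0 (an empty ground truth answered by an empty result is
correct); one empty table against a non-empty one scores 0.0 (follows from
the formula); two empty row-sets have Jaccard 1.0.

The assignment step pads the similarity matrix to square and solves it with
`clue::solve_LSAP`. Ties in the optimal matching cannot affect the score
(the total weight is unique); the reported pair set is deterministic, and
zero-weight pairs are omitted from it. The metric is deliberately lexical:
`Mouse` vs `Mus musculus` scores zero. That is a known property, not a bug
to fix here — entity normalisation belongs upstream of scoring.

## Synthetic fixtures and what they do (not) show

The generator emulates the structural premise of curated RDF databases:
every entry instantiates the same tree-shaped subgraph. `random_schema()`
draws forests with connectors and explanations; `generate_fixture_graph()`
mints deterministic subject IRIs, one type triple per root type and one
triple per edge per entry, with leaf values drawn reproducibly from value
pools (default pools of three values per variable give entries overlapping,
filterable values). `oracle_answer()` answers a request by walking the
parsed graph along schema paths directly — no query text, no SPARQL
machinery — and is the independent standard the pipeline is checked against.

Passing these checks shows the builder, renderer, parser and evaluator are
mutually consistent and sound on schema-conforming graphs. It does **not**
show anything about linguistic robustness of extraction on real questions,
about real endpoints (drift, truncation, latency), or about schemas that
violate the one-pattern-per-entry premise.

Problem sizes used by the checks, chosen to exercise every code path while
keeping the whole suite near a minute on one CPU: round-trips over 50 random
schemas; 500 random queries against an independent SPARQL 1.1 grammar
(Python `rdflib`); matching vs exhaustive assignment on 200 matrices up to
6×6; pipeline-vs-oracle equality on 100 random (schema, graph, request)
draws with 2–5 entries; 1000 fuzzed answer-block round-trips; four-record
campaigns for the report arithmetic.

## Campaigns

`run_campaign()` scores each benchmark record on three axes: execution-based
table similarity, variable-set Jaccard, and parameter-set Jaccard over exact
(variable, value) pairs, plus strict-copy warning counts. A record whose
extraction, build or execution fails scores 0 for table similarity and is
flagged — distinct from a legitimate empty-vs-empty result, which scores 1 —
and never aborts the campaign. Ground truth is stored as variables +
parameters (the form experts curate), and truth queries are derived by the
same builder, so variable/parameter scores measure extraction in isolation.
Reports carry seed, mode and client id; with the mock client, fixed-seed
reruns are byte-identical.

## Known limitations

* The YAML dialect is a compatible subset; upstream schemas using constructs
  outside it must be simplified before use.
* The local evaluator covers only the emitted dialect — it is not a general
  SPARQL engine, and hand-written queries using unsupported constructs are
  rejected.
* The metric's lexical strictness means semantically correct but differently
  written answers score 0.
* Paraphrase generation for benchmarks is out of scope; records only carry
  paraphrase links.
* No hosted language model is bundled; real-model runs require the caller to
  wrap their client in `llm_client()`.
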