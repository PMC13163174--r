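# sparqlgen

Natural-language questions over biological RDF databases (UniProt-style
protein stores, reaction and expression databases) require SPARQL, and the
schemas of these knowledge graphs are too intricate for most scientists to
query by hand. LLMs can write SPARQL directly, but they hallucinate
structure. `sparqlgen` takes the two-stage route instead: a language model is
asked only to **extract** — which schema variables the question wants, and
which (variable, value) conditions constrain it — and a deterministic,
schema-driven builder then assembles a syntactically valid SPARQL SELECT
query. The model never sees SPARQL syntax, so structural hallucination is
impossible by construction and model-induced errors stay isolated in the
extraction step.

The package provides, end to end and fully offline-testable:

* **Schema model** — curated YAML schemas describing a database's RDF model
  as a forest of human-readable variables with example values and
  explanations (`parse_schema()`, `render_schema()`, `merge_schemas()` for
  cross-database questions, `list_selectable_variables()` which hides
  connector nodes).
* **Query builder** — `build_query()` traverses the schema tree from each
  root to the requested variables, emitting the property-path triple
  patterns, `SELECT DISTINCT`, and one `VALUES` block per constrained
  variable; rendering is byte-deterministic.
* **Extraction** — a four-step chain-of-thought prompt (extract requests →
  map to variables → extract conditions → map to parameters), a pluggable
  `llm_client()` contract with a deterministic `mock_llm_client()` for
  offline use, strict validation of the model's fenced answer block, and a
  strict-copy guard that flags condition values not copied verbatim from the
  question (e.g. a reaction equation whose `=` drifted to `=>`).
* **Execution** — `execute_local()` runs the emitted query dialect in-process
  over Turtle graphs; `execute_remote()` speaks the SPARQL Protocol
  (JSON/XML results) with injectable transport.
* **Evaluation** — the execution-based metric for comparing a generated
  query against an expert-written one by what they *return*, not how they
  are written.
* **Fixtures & campaigns** — synthetic schema and graph generators, a
  traversal oracle that answers requests without any SPARQL, and
  `run_campaign()` for scored benchmark runs with per-record and aggregate
  reports.

## The metric

A SPARQL result is a table whose rows are value sets. For a ground-truth
table *G* (N<sub>g</sub> rows) and a generated table *Q* (N<sub>q</sub>
rows), every row pair gets the Jaccard coefficient
J(G<sub>i</sub>, Q<sub>j</sub>) = |G<sub>i</sub> ∩ Q<sub>j</sub>| /
|G<sub>i</sub> ∪ Q<sub>j</sub>|, giving an N<sub>g</sub> × N<sub>q</sub>
similarity matrix *S*. A maximum-weight one-to-one matching *M* over *S* is
solved (assignment problem), and the score is

&nbsp;&nbsp;&nbsp;&nbsp;score(G, Q) = ( Σ<sub>(i,j)∈M</sub> S<sub>ij</sub> ) / max(N<sub>g</sub>, N<sub>q</sub>)

so unmatched rows in the larger table are penalised. Variable selection and
parameter extraction are additionally scored by plain set Jaccard over names
and exact (variable, value) pairs (`set_jaccard()`), and score distributions
are summarised in five bins (`score_distribution()`): x=0, 0&lt;x&lt;0.5,
x=0.5, 0.5&lt;x&lt;1, x=1.

## Worked example

A miniature protein schema and a three-entry graph (two human entries) ship
under `inst/extdata/`. Retrieve citation IDs of human (taxonomy 9606)
proteins:

```r
library(sparqlgen)
sch <- read_schema(system.file("extdata", "uniprot_demo.yaml", package = "sparqlgen"))
q <- build_query(sch, query_request(
  "uniprot_citation",
  parameters = list(c("uniprot_taxonomy", "taxonomy:9606"))))
cat(q$text)
#> PREFIX taxonomy: <http://purl.uniprot.org/taxonomy/>
#> PREFIX up: <http://purl.uniprot.org/core/>
#>
#> SELECT DISTINCT ?uniprot_citation
#> WHERE {
#>   ?UniProt a up:Protein .
#>   ?UniProt up:organism ?uniprot_taxonomy .
#>   ?UniProt up:citation ?uniprot_citation .
#>   VALUES ?uniprot_taxonomy { taxonomy:9606 }
#> }

execute_local(q$text, system.file("extdata", "uniprot_demo.ttl", package = "sparqlgen"))
#> <result_table> 2 rows
#>   {http://purl.uniprot.org/citations/15174051}
#>   {http://purl.uniprot.org/citations/23792563}
```

The query selects only the requested variable; the taxonomy constraint lives
in the `VALUES` block, and the builder resolved the two property paths from
the schema tree. Two of the three fixture entries are human, hence two rows.
Scoring two tables that agree on two of three distinct rows:

```r
table_similarity(result_table(list("a", "b", "c")),
                 result_table(list("a", "b", "x")))
#> [1] 0.6666667
```

A command-line surface wrapping the same functions (subcommands `generate`,
`extract`, `ask`, `benchmark`, `eval-tables`, `make-fixture`) is installed at
`system.file("cli", "sparqlgen.R", package = "sparqlgen")`.

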