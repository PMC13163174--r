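# Shared fixtures and independent oracles used across the suite.

demo_schema <- function() {
  read_schema(system.file("extdata", "uniprot_demo.yaml",
                          package = "sparqlgen"))
}

demo_graph_path <- function() {
  system.file("extdata", "uniprot_demo.ttl", package = "sparqlgen")
}

demo_request <- function() {
  query_request("uniprot_citation",
                parameters = list(c("uniprot_taxonomy", "taxonomy:9606")))
}

# Schema with a connector between root and leaf.
connector_schema <- function() {
  parse_schema("
prefixes:
  ex: <http://example.org/c/>
model:
  - Entry ex:e1:
      - a: ex:Entry
      - ex:annotation:
          - note: \"\"
          - ex:text:
              note_text: sample_text
")
}

# Random request against a schema: 1-3 selectable variables, sometimes a
# parameter whose value is drawn from the given pools (or synthesized).
rand_request <- function(schema, pools = NULL, p_param = 0.6) {
  sel <- list_selectable_variables(schema)$name
  vars <- sample(sel, sample.int(min(3L, length(sel)), 1L))
  params <- list()
  if (stats::runif(1) < p_param) {
    pv <- sample(sel, 1L)
    val <- if (!is.null(pools) && pv %in% names(pools)) {
      sample(pools[[pv]], 1L)
    } else {
      paste0(pv, "_", sample.int(3L, 1L))
    }
    params <- list(c(pv, val))
  }
  query_request(vars, params)
}

# Value pools giving fixture graphs overlapping, filterable values.
rand_pools <- function(schema) {
  sel <- list_selectable_variables(schema)
  leafs <- sel$name[!sel$name %in% schema$roots]
  pools <- lapply(leafs, function(v) paste0(v, "_", 1:3))
  stats::setNames(pools, leafs)
}

# Exhaustive maximum-weight matching over all injective row assignments;
# the brute-force oracle for the assignment step.
brute_force_matching_weight <- function(S) {
  ng <- nrow(S)
  nq <- ncol(S)
  if (ng == 0L || nq == 0L) return(0)
  if (ng > nq) return(brute_force_matching_weight(t(S)))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[[i]], rest)
    }
    out
  }
  best <- 0
  for (cols in utils::combn(nq, ng, simplify = FALSE)) {
    for (ord in perms(cols)) {
      best <- max(best, sum(S[cbind(seq_len(ng), ord)]))
    }
  }
  best
}

# Independent SPARQL 1.1 grammar check through Python rdflib. Queries are
# joined with a sentinel line; returns the number that failed to parse.
sparql_parse_failures <- function(queries) {
  qfile <- tempfile(fileext = ".txt")
  writeLines(paste(queries, collapse = "\n###QUERY###\n"), qfile,
             useBytes = TRUE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from rdflib.plugins.sparql import prepareQuery",
    "text = open(sys.argv[1], encoding='utf-8').read()",
    "bad = 0",
    "for q in text.split('\\n###QUERY###\\n'):",
    "    try:",
    "        prepareQuery(q)",
    "    except Exception as e:",
    "        bad += 1",
    "        sys.stderr.write(str(e)[:200] + '\\n')",
    "print(bad)"
  ), script)
  out <- system2("python", c(script, qfile), stdout = TRUE, stderr = FALSE)
  as.integer(out[[length(out)]])
}

# Execute a query over a Turtle graph with Python rdflib (independent engine).
rdflib_execute <- function(query_text, ttl) {
  tfile <- tempfile(fileext = ".ttl")
  writeLines(ttl, tfile, useBytes = TRUE)
  qfile <- tempfile(fileext = ".rq")
  writeLines(query_text, qfile, useBytes = TRUE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, rdflib",
    "g = rdflib.Graph(); g.parse(sys.argv[1], format='turtle')",
    "q = open(sys.argv[2], encoding='utf-8').read()",
    "for row in g.query(q):",
    "    cells = []",
    "    for v in row:",
    "        if v is None: continue",
    "        cells.append(str(v))",
    "    print('\\t'.join(cells))"
  ), script)
  out <- system2("python", c(script, tfile, qfile), stdout = TRUE,
                 stderr = FALSE)
  out <- out[nzchar(out)]
  result_table(strsplit(out, "\t", fixed = TRUE))
}

# Scripted answer block for a mock client.
answer_block <- function(variables, parameters = list(), prose = "") {
  res <- structure(
    list(variables = variables,
         parameters = if (length(parameters)) {
           do.call(rbind, lapply(parameters, function(p)
             data.frame(variable = p[[1]], value = p[[2]],
                        stringsAsFactors = FALSE)))
         } else {
           data.frame(variable = character(0), value = character(0),
                      stringsAsFactors = FALSE)
         }),
    class = "extraction_result")
  paste0(prose, "\n", serialize_extraction(res))
}

# Four-record benchmark on the miniature protein schema.
demo_benchmark <- function() {
  list(
    list(id = "q1", question = "Citations for human proteins?",
         truth_variables = list("uniprot_citation"),
         truth_parameters = list(list("uniprot_taxonomy", "taxonomy:9606"))),
    list(id = "q2", question = "Which taxa are covered?",
         truth_variables = list("uniprot_taxonomy"),
         truth_parameters = list()),
    list(id = "q3", question = "List protein entries with citations.",
         truth_variables = list("UniProt", "uniprot_citation"),
         truth_parameters = list()),
    list(id = "q4", question = "Citations of mouse proteins (taxonomy:10090)?",
         truth_variables = list("uniprot_citation"),
         truth_parameters = list(list("uniprot_taxonomy", "taxonomy:10090")))
  )
}

# Mock client scripted with each record's ground truth.
perfect_client <- function(records) {
  answers <- vapply(records, function(r) {
    answer_block(unlist(r$truth_variables),
                 lapply(r$truth_parameters, unlist),
                 prose = paste("Step 1: ...", "Step 2: ...",
                               "Step 3: ...", "Step 4: ...", sep = "\n"))
  }, character(1))
  mock_llm_client(stats::setNames(answers, vapply(records, `[[`, character(1),
                                                  "question")))
}
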