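test_that("the restricted Turtle reader handles the emitted constructs", {
  ttl <- '
@prefix ex: <http://example.org/> .
# a comment
ex:s1 a ex:Thing ;
    ex:p "plain" , "typed"^^<http://www.w3.org/2001/XMLSchema#string> ;
    ex:q "tagged"@en .
<http://example.org/s2> ex:p _:b0 .
_:b0 ex:q "nested \\"quote\\"" .
'
  g <- parse_turtle(ttl)
  expect_identical(nrow(g$triples), 6L)
  expect_identical(g$prefixes[["ex"]], "http://example.org/")
  expect_true(term_iri("http://example.org/s2") %in% g$triples$s)
  expect_true("_:b0" %in% g$triples$o)
  # serializer round-trip preserves the triple set
  back <- parse_turtle(render_turtle(g))
  expect_identical(back$triples, g$triples)
  expect_error(parse_turtle("ex:s ex:p"), "unexpected end|undeclared")
})

test_that("local execution of the worked query returns the human rows", {
  sch <- demo_schema()
  q <- build_query(sch, demo_request())
  tab <- execute_local(q$text, demo_graph_path())
  expect_length(tab$rows, 2L)
  expect_setequal(unlist(tab$rows),
                  c("http://purl.uniprot.org/citations/15174051",
                    "http://purl.uniprot.org/citations/23792563"))
  # repeated execution is identical
  expect_identical(execute_local(q$text, demo_graph_path()), tab)
})

test_that("an empty graph yields zero rows", {
  sch <- demo_schema()
  q <- build_query(sch, query_request("UniProt"))
  tab <- execute_local(q$text, "@prefix ex: <http://example.org/> .")
  expect_length(tab$rows, 0L)
})

test_that("VALUES with several terms acts as a disjunction", {
  sch <- demo_schema()
  q <- build_query(sch, query_request(
    "uniprot_citation",
    list(c("uniprot_taxonomy", "taxonomy:9606"),
         c("uniprot_taxonomy", "taxonomy:10090"))))
  tab <- execute_local(q$text, demo_graph_path())
  expect_length(tab$rows, 3L)
})

test_that("the local evaluator agrees with an independent SPARQL engine", {
  sch <- demo_schema()
  ttl <- paste(readLines(demo_graph_path()), collapse = "\n")
  reqs <- list(
    demo_request(),
    query_request(c("UniProt", "uniprot_citation")),
    query_request("uniprot_taxonomy"),
    query_request("uniprot_citation",
                  list(c("uniprot_taxonomy", "taxonomy:999")))
  )
  for (req in reqs) {
    q <- build_query(sch, req)
    mine <- execute_local(q$text, ttl)
    theirs <- rdflib_execute(q$text, ttl)
    expect_equal(table_similarity(mine, theirs), 1)
  }
})

test_that("remote execution parses protocol responses and errors distinctly", {
  json_body <- jsonlite::toJSON(list(
    head = list(vars = list("x")),
    results = list(bindings = list(
      list(x = list(type = "uri", value = "http://example.org/a")),
      list(x = list(type = "literal", value = "b",
                    `xml:lang` = "en"))
    ))), auto_unbox = TRUE)
  xml_body <- paste0(
    '<?xml version="1.0"?>',
    '<sparql xmlns="http://www.w3.org/2005/sparql-results#">',
    '<head><variable name="x"/></head><results>',
    '<result><binding name="x"><uri>http://example.org/a</uri></binding></result>',
    '<result><binding name="x"><literal xml:lang="en">b</literal></binding></result>',
    "</results></sparql>")
  mk <- function(body, type) {
    endpoint_config("http://mock.test/sparql",
                    transport = function(ep, q)
                      list(status = 200L, content_type = type, body = body))
  }
  tj <- execute_remote("SELECT ?x WHERE { ?s ?p ?x }", mk(json_body, "application/sparql-results+json"))
  tx <- execute_remote("SELECT ?x WHERE { ?s ?p ?x }", mk(xml_body, "application/sparql-results+xml"))
  expect_length(tj$rows, 2L)
  expect_identical(tj$rows, tx$rows)  # cross-format equivalence
  expect_identical(tj$rows[[1]], "http://example.org/a")
  expect_identical(tj$rows[[2]], "b")  # language tag stripped

  http_fail <- endpoint_config("http://mock.test/sparql",
                               transport = function(ep, q)
                                 list(status = 503L, content_type = "", body = ""))
  expect_error(execute_remote("SELECT ?x WHERE {}", http_fail),
               class = "sparql_http_error")
  bad_json <- mk("{not json", "application/sparql-results+json")
  expect_error(execute_remote("SELECT ?x WHERE {}", bad_json),
               class = "sparql_results_error")
  transport_fail <- endpoint_config(
    "http://mock.test/sparql",
    transport = function(ep, q) stop(sparqlgen:::sparql_error(
      "transport", "connection refused")))
  expect_error(execute_remote("SELECT ?x WHERE {}", transport_fail),
               class = "sparql_transport_error")
  expect_error(endpoint_config("not a url"), "http")
})

test_that("local and mocked-remote execution of one graph agree", {
  sch <- demo_schema()
  ttl <- paste(readLines(demo_graph_path()), collapse = "\n")
  # endpoint whose transport serves the same graph through the JSON protocol
  serve <- function(ep, query_text) {
    tab <- execute_local(query_text, ttl)
    q <- sparqlgen:::parse_sparql_subset(query_text)
    # rebuild protocol bindings from raw (non-normalised) execution
    sols <- sparqlgen:::evaluate_bgp(q$patterns, parse_turtle(ttl)$triples)
    for (vb in q$values) {
      sols <- Filter(function(sol) sol[[vb$variable]] %in% vb$terms, sols)
    }
    bindings <- lapply(sols, function(sol) {
      cells <- lapply(q$select_vars, function(v) {
        val <- sol[[v]]
        if (startsWith(val, "<")) {
          list(type = "uri", value = substr(val, 2L, nchar(val) - 1L))
        } else if (startsWith(val, "_:")) {
          list(type = "bnode", value = substring(val, 3L))
        } else {
          list(type = "literal",
               value = sparqlgen:::unescape_literal(
                 sub('^"(.*)"(\\^\\^.*|@.*)?$', "\\1", val)))
        }
      })
      stats::setNames(cells, q$select_vars)
    })
    body <- jsonlite::toJSON(list(head = list(vars = q$select_vars),
                                  results = list(bindings = bindings)),
                             auto_unbox = TRUE)
    list(status = 200L, content_type = "application/sparql-results+json",
         body = body)
  }
  ep <- endpoint_config("http://mock.test/sparql", transport = serve)
  for (req in list(demo_request(), query_request("uniprot_taxonomy"))) {
    q <- build_query(sch, req)
    local_tab <- execute_local(q$text, ttl)
    remote_tab <- execute_remote(q$text, ep)
    # remote bindings carry duplicates that DISTINCT removed locally
    expect_equal(table_similarity(local_tab, result_table(
      remote_tab$rows[!duplicated(vapply(remote_tab$rows, paste,
                                         character(1), collapse = "\r"))])),
      1)
  }
})

test_that("truncation at the configured limit raises a warning", {
  body <- jsonlite::toJSON(list(results = list(bindings = list(
    list(x = list(type = "literal", value = "a")),
    list(x = list(type = "literal", value = "b"))
  ))), auto_unbox = TRUE)
  ep <- endpoint_config("http://mock.test/sparql", limit = 2,
                        transport = function(e, q)
                          list(status = 200L,
                               content_type = "application/json", body = body))
  expect_warning(execute_remote("SELECT ?x WHERE { ?s ?p ?x }", ep),
                 "truncated")
})

test_that("blank nodes normalise to a stable per-table sequence", {
  ttl <- '
@prefix ex: <http://example.org/> .
ex:s1 a ex:T .
ex:s1 ex:p _:first .
ex:s2 a ex:T .
ex:s2 ex:p _:second .
'
  q <- "PREFIX ex: <http://example.org/>\nSELECT DISTINCT ?o WHERE { ?s ex:p ?o . }"
  t1 <- execute_local(q, ttl)
  t2 <- execute_local(q, ttl)
  expect_identical(t1$rows, t2$rows)
  expect_setequal(unlist(t1$rows), c("_:b1", "_:b2"))
})
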