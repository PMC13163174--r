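test_that("fixture graphs carry one triple per type and edge per entry", {
  sch <- demo_schema()
  ttl <- generate_fixture_graph(fixture_spec(sch, 3, seed = 5))
  g <- parse_turtle(ttl)
  expect_identical(nrow(g$triples), 9L)  # 3 type + 3 organism + 3 citation

  lone <- parse_schema("
prefixes:
  ex: <http://example.org/>
model:
  - Lonely ex:l1:
      - a: ex:Lonely
")
  g1 <- parse_turtle(generate_fixture_graph(fixture_spec(lone, 1, seed = 5)))
  expect_identical(nrow(g1$triples), 1L)
})

test_that("fixture generation is a deterministic function of its spec", {
  set.seed(3)
  sch <- random_schema(n_nodes = 4L, tag = "det")
  spec <- fixture_spec(sch, 10, seed = 42,
                       value_pools = list())
  expect_identical(generate_fixture_graph(spec), generate_fixture_graph(spec))
  # and does not disturb the caller's RNG stream
  set.seed(1)
  a <- stats::runif(1)
  set.seed(1)
  invisible(generate_fixture_graph(spec))
  b <- stats::runif(1)
  expect_identical(a, b)
})

test_that("connector nodes become intermediate blank nodes", {
  sch <- connector_schema()
  ttl <- generate_fixture_graph(fixture_spec(sch, 2, seed = 9))
  g <- parse_turtle(ttl)
  expect_true(any(startsWith(g$triples$o, "_:")))
  # and the pipeline still reaches through them
  q <- build_query(sch, query_request("note_text"))
  tab <- execute_local(q$text, ttl)
  expect_length(tab$rows, length(unique(
    g$triples$o[endsWith(g$triples$p, "/text>")])))
})

test_that("the traversal oracle answers parameterised requests", {
  sch <- demo_schema()
  ttl <- paste(readLines(demo_graph_path()), collapse = "\n")
  tab <- oracle_answer(sch, demo_request(), ttl)
  expect_length(tab$rows, 2L)
  none <- oracle_answer(sch, query_request(
    "uniprot_citation", list(c("uniprot_taxonomy", "taxonomy:404"))), ttl)
  expect_length(none$rows, 0L)
})

test_that("query pipeline and traversal oracle agree on random fixtures", {
  set.seed(83)
  for (k in 1:25) {
    sch <- random_schema(n_nodes = 4L, max_roots = 2L, tag = paste0("e2e", k))
    pools <- rand_pools(sch)
    ttl <- generate_fixture_graph(
      fixture_spec(sch, n_entries = sample(2:6, 1L), seed = k,
                   value_pools = pools))
    req <- rand_request(sch, pools)
    got <- execute_local(build_query(sch, req)$text, ttl)
    want <- oracle_answer(sch, req, ttl)
    expect_equal(table_similarity(want, got), 1)
    expect_identical(length(got$rows), length(want$rows))
  }
})

test_that("benchmark files round-trip and validate", {
  recs <- demo_benchmark()
  path <- tempfile(fileext = ".yaml")
  write_benchmark(recs, path)
  back <- read_benchmark(path)
  expect_length(back, 4L)
  expect_identical(back[[1]]$question, recs[[1]]$question)
  expect_identical(back[[1]]$truth_parameters[[1]],
                   c("uniprot_taxonomy", "taxonomy:9606"))
  bad <- recs
  bad[[2]]$id <- bad[[1]]$id
  expect_error(sparqlgen:::validate_benchmark(bad), "unique")
  bad2 <- recs
  bad2[[2]]$paraphrase_of <- "ghost"
  expect_error(sparqlgen:::validate_benchmark(bad2), "unknown record")
})

test_that("a perfect mock scores 1.0 on every axis", {
  sch <- demo_schema()
  recs <- demo_benchmark()
  report <- run_campaign(recs, sch, perfect_client(recs), demo_graph_path(),
                         seed = 11)
  expect_equal(unname(report$means),
               c(1, 1, 1))
  expect_identical(unname(report$bins$table_similarity),
                   c(0L, 0L, 0L, 0L, 4L))
  expect_false(any(report$per_record$failed))
})

test_that("one failing extraction of four gives mean table similarity 0.75", {
  sch <- demo_schema()
  recs <- demo_benchmark()
  answers <- vapply(recs, function(r)
    answer_block(unlist(r$truth_variables),
                 lapply(r$truth_parameters, unlist)), character(1))
  answers[[2]] <- answer_block("hallucinated_variable")
  client <- mock_llm_client(stats::setNames(
    answers, vapply(recs, `[[`, character(1), "question")))
  report <- run_campaign(recs, sch, client, demo_graph_path(), seed = 11)
  expect_equal(unname(report$means[["table_similarity"]]), 0.75)
  expect_identical(report$per_record$failed, c(FALSE, TRUE, FALSE, FALSE))
  expect_match(report$per_record$error[[2]], "hallucinated_variable")
  # bins conserve the record count
  expect_identical(sum(report$bins$table_similarity), 4L)
})

test_that("corrupting more extractions never raises the mean score", {
  sch <- demo_schema()
  recs <- demo_benchmark()
  truth <- vapply(recs, function(r)
    answer_block(unlist(r$truth_variables),
                 lapply(r$truth_parameters, unlist)), character(1))
  qs <- vapply(recs, `[[`, character(1), "question")
  means <- vapply(0:4, function(n_bad) {
    answers <- truth
    if (n_bad > 0L) {
      for (i in seq_len(n_bad)) answers[[i]] <- answer_block("no_such_var")
    }
    report <- run_campaign(recs, sch,
                           mock_llm_client(stats::setNames(answers, qs)),
                           demo_graph_path(), seed = 11)
    report$means[["table_similarity"]]
  }, numeric(1))
  expect_true(all(diff(means) <= 0))
  expect_equal(means[[1]], 1)
  expect_equal(means[[5]], 0)
})

test_that("campaign reports are reproducible and internally consistent", {
  sch <- demo_schema()
  recs <- demo_benchmark()
  client <- perfect_client(recs)
  r1 <- run_campaign(recs, sch, client, demo_graph_path(), seed = 19)
  r2 <- run_campaign(recs, sch, client, demo_graph_path(), seed = 19)
  expect_identical(r1, r2)
  p1 <- tempfile(fileext = ".json")
  p2 <- tempfile(fileext = ".json")
  report_record(r1, p1)
  report_record(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # report conservation: means recomputable from per-record scores
  expect_equal(r1$means[["table_similarity"]],
               mean(r1$per_record$table_similarity), tolerance = 1e-12)
  expect_identical(sum(r1$bins$variable_jaccard), nrow(r1$per_record))
  txt <- format_report_text(r1)
  expect_match(txt, "table_similarity\\s+1\\.000")
})
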