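step_headings <- c("Step 1: Extracting User Requests",
                   "Step 2: Converting User Request to Variables",
                   "Step 3: Extracting User-Specified Condition",
                   "Step 4: Converting Conditions to Parameters")

rand_string <- function(n = 12L, pool = c(letters, LETTERS, 0:9, " ", "-",
                                          "_", ":", "=", "+", "(", ")")) {
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

test_that("the variables-info listing is line-per-variable and injective", {
  sch <- demo_schema()
  listing <- format_variables_info(list_selectable_variables(sch))
  lines <- strsplit(listing, "\n")[[1]]
  expect_length(lines, 3L)
  expect_true(any(grepl("uniprot_taxonomy", lines)))
  expect_true(any(grepl("Taxonomy ID", lines)))

  one <- format_variables_info(data.frame(name = "v", example = "x",
                                          explanation = ""))
  expect_identical(one, "v | x | ")
  expect_error(format_variables_info(list_selectable_variables(sch)[0, ]),
               "at least one")

  # injective on names: flipping one name always changes the string
  set.seed(71)
  for (k in 1:30) {
    d1 <- data.frame(name = paste0("n", sample.int(50L, 3L)),
                     example = "e", explanation = "x")
    d2 <- d1
    i <- sample.int(3L, 1L)
    d2$name[[i]] <- paste0(d2$name[[i]], "z")
    expect_false(identical(format_variables_info(d1),
                           format_variables_info(d2)))
  }
})

test_that("the prompt carries the question, listing and four steps in order", {
  sch <- demo_schema()
  info <- format_variables_info(list_selectable_variables(sch))
  question <- "What is the protein ID of ACE2 gene registered in UniProt?"
  bundle <- build_extraction_prompt(question, info)
  expect_s3_class(bundle, "prompt_bundle")
  expect_true(grepl(question, bundle$user_text, fixed = TRUE))
  expect_true(grepl(info, bundle$user_text, fixed = TRUE))
  pos <- vapply(step_headings, function(h)
    regexpr(h, bundle$user_text, fixed = TRUE)[[1]], numeric(1))
  expect_true(all(pos > 0))
  expect_identical(order(pos), 1:4)
  expect_error(build_extraction_prompt("", info), "non-empty")

  set.seed(73)
  for (k in 1:100) {
    b <- build_extraction_prompt(rand_string(), info)
    expect_false(grepl("{user_question}", b$user_text, fixed = TRUE))
    expect_false(grepl("{variables_info}", b$user_text, fixed = TRUE))
  }
})

test_that("answer blocks parse back to the request they encode", {
  sch <- demo_schema()
  raw <- paste0(
    "Step 1: the user wants citations.\n",
    "Step 2: uniprot_citation.\n",
    "Step 3: human proteins, taxonomy: 9606.\n",
    "Step 4: uniprot_taxonomy = taxonomy:9606.\n",
    "```json\n",
    "{\"variables\": [\"uniprot_citation\"],",
    " \"parameters\": [[\"uniprot_taxonomy\", \"taxonomy:9606\"]]}\n",
    "```\n")
  res <- parse_extraction_output(raw, sch)
  expect_identical(res$variables, "uniprot_citation")
  expect_identical(res$parameters$variable, "uniprot_taxonomy")
  expect_identical(res$parameters$value, "taxonomy:9606")
  expect_identical(res$trace, raw)

  expect_error(parse_extraction_output("no block here", sch),
               "no fenced answer block")
  expect_error(parse_extraction_output("```json\n{broken\n```", sch),
               "unparseable")
  expect_error(parse_extraction_output(
    "```json\n{\"variables\": [\"protein_id\"], \"parameters\": []}\n```",
    sch), "protein_id")
  expect_error(parse_extraction_output(
    paste0("```json\n{\"variables\": [\"UniProt\", \"UniProt\"],",
           " \"parameters\": []}\n```"), sch), "duplicate")
  expect_error(parse_extraction_output(
    paste0("```json\n{\"variables\": [],",
           " \"parameters\": [[\"UniProt\", \"\"]]}\n```"), sch),
    "empty value")
})

test_that("serialize-embed-parse is the identity on fuzzed results", {
  sch <- demo_schema()
  vars_pool <- names(sch$nodes)
  set.seed(79)
  for (k in 1:200) {
    nv <- sample.int(3L, 1L)
    vars <- sample(vars_pool, nv)
    np <- sample.int(3L, 1L) - 1L
    params <- if (np > 0L) {
      data.frame(variable = sample(vars_pool, np, replace = TRUE),
                 value = vapply(seq_len(np), function(i)
                   rand_string(sample.int(20L, 1L)), character(1)),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(variable = character(0), value = character(0),
                 stringsAsFactors = FALSE)
    }
    params <- params[nzchar(params$value), , drop = FALSE]
    orig <- structure(list(variables = vars, parameters = params),
                      class = "extraction_result")
    embedded <- paste0("Reasoning prose ", rand_string(), "\n",
                       serialize_extraction(orig),
                       "\ntrailing prose ", rand_string(), "\n")
    back <- parse_extraction_output(embedded, sch)
    expect_identical(back$variables, vars)
    expect_identical(back$parameters$variable, params$variable)
    expect_identical(back$parameters$value, params$value)
  }
})

test_that("strict-copy guard flags values not copied verbatim", {
  question <- paste0("Which reaction matches angiotensin II + H2O = ",
                     "angiotensin-(1-7) + L-phenylalanine?")
  drifted <- structure(
    list(parameters = data.frame(
      variable = "rhea_equation",
      value = "angiotensin II + H2O => angiotensin-(1-7) + L-phenylalanine",
      stringsAsFactors = FALSE)),
    class = "extraction_result")
  w <- check_strict_copy(drifted, question)
  expect_length(w, 1L)
  expect_match(w, "not a verbatim substring")

  ok <- structure(
    list(parameters = data.frame(variable = "gene", value = "ACE2",
                                 stringsAsFactors = FALSE)),
    class = "extraction_result")
  expect_length(check_strict_copy(ok, "Tell me about the ACE2 gene"), 0L)

  # the guard checks the question, not database terminology
  cells <- structure(
    list(parameters = data.frame(variable = "anat", value = "breast cells",
                                 stringsAsFactors = FALSE)),
    class = "extraction_result")
  expect_length(check_strict_copy(cells, "Expression in breast cells?"), 0L)
  # and it is case-sensitive
  lower <- structure(
    list(parameters = data.frame(variable = "gene", value = "ace2",
                                 stringsAsFactors = FALSE)),
    class = "extraction_result")
  expect_length(check_strict_copy(lower, "Tell me about the ACE2 gene"), 1L)
})

test_that("the mock-client pipeline is pure and surfaces errors unchanged", {
  sch <- demo_schema()
  scripted <- answer_block("uniprot_citation",
                           list(c("uniprot_taxonomy", "taxonomy:9606")),
                           prose = paste(step_headings, collapse = "\n"))
  client <- mock_llm_client(scripted)
  q <- "Citations for human (taxonomy:9606) proteins?"
  r1 <- extract_request(q, sch, client)
  r2 <- extract_request(q, sch, client)
  expect_identical(r1, r2)
  expect_identical(r1$variables, "uniprot_citation")
  expect_identical(r1$parameters$value, "taxonomy:9606")
  expect_length(r1$warnings, 0L)
  expect_s3_class(as_query_request(r1), "query_request")

  bad <- mock_llm_client(answer_block("protein_id"))
  expect_error(extract_request(q, sch, bad), "protein_id")
})

test_that("all three presentation modes yield well-formed prompts", {
  sch <- connector_schema()
  client_capture <- new.env()
  probe <- llm_client(function(bundle) {
    client_capture$prompt <- bundle$user_text
    answer_block("note_text")
  }, model_id = "probe")
  q <- "What text is attached to each entry?"
  for (mode in c("VwE", "VwoE", "VinS")) {
    res <- extract_request(q, sch, probe, mode = mode)
    expect_identical(res$variables, "note_text")
    expect_true(grepl(q, client_capture$prompt, fixed = TRUE))
    for (h in step_headings) {
      expect_true(grepl(h, client_capture$prompt, fixed = TRUE))
    }
    if (mode != "VinS") {
      # connector names never leak into listing-based prompts
      expect_false(grepl("note |", client_capture$prompt, fixed = TRUE))
    }
  }
  # VwoE omits the explanation sentences that VwE carries
  extract_request(q, sch, probe, mode = "VwE",
                  explanations = c(note_text = "A curated sentence."))
  expect_true(grepl("A curated sentence.", client_capture$prompt, fixed = TRUE))
  extract_request(q, sch, probe, mode = "VwoE",
                  explanations = c(note_text = "A curated sentence."))
  expect_false(grepl("A curated sentence.", client_capture$prompt,
                     fixed = TRUE))
})
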