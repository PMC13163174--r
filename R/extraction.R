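# Extraction stage: variable listing -> four-step prompt -> pluggable
# language-model client -> validated request. The model never writes SPARQL;
# it only selects schema variable names and copies condition values out of
# the question, which keeps model-induced errors isolated from query syntax.

#' Format the variables-info listing shown to the extraction model
#'
#' One line per variable: `name | example | explanation`, in input order.
#' Injective on names, deterministic.
#'
#' @param descriptions Data frame as returned by
#'   [list_selectable_variables()] (columns `name`, `example`,
#'   `explanation`), non-empty.
#' @param include_explanations When `FALSE`, the explanation column is left
#'   blank (the names-only presentation mode).
#' @return A single multi-line string.
#' @export
format_variables_info <- function(descriptions, include_explanations = TRUE) {
  stopifnot(is.data.frame(descriptions),
            all(c("name", "example", "explanation") %in% names(descriptions)))
  if (nrow(descriptions) == 0L) {
    stop("variables-info listing must contain at least one variable",
         call. = FALSE)
  }
  expl <- if (include_explanations) descriptions$explanation else ""
  paste0(descriptions$name, " | ", descriptions$example, " | ", expl,
         collapse = "\n")
}

#' Build the four-step extraction prompt
#'
#' Substitutes the question and the variables listing into the prompt
#' template. The template walks the model through four steps — extracting
#' user requests, converting requests to variables, extracting user-specified
#' conditions, and converting conditions to parameters — and demands a final
#' fenced `json` answer block with keys `variables` and `parameters`.
#'
#' @param question Non-empty question text.
#' @param variables_info Listing from [format_variables_info()] (or raw
#'   schema text in the whole-schema presentation mode).
#' @param template Optional custom template string containing the
#'   `{user_question}` and `{variables_info}` slots; defaults to the template
#'   shipped with the package.
#' @return An object of class `prompt_bundle` with elements `system_text`,
#'   `user_text`, `question`.
#' @export
build_extraction_prompt <- function(question, variables_info,
                                    template = NULL) {
  if (!is.character(question) || length(question) != 1L || !nzchar(question)) {
    stop("question must be a non-empty string", call. = FALSE)
  }
  if (is.null(template)) template <- default_prompt_template()
  for (slot in c("{user_question}", "{variables_info}")) {
    if (!grepl(slot, template, fixed = TRUE)) {
      stop("prompt template lacks the ", slot, " slot", call. = FALSE)
    }
  }
  user <- sub("{user_question}", question, template, fixed = TRUE)
  user <- sub("{variables_info}", variables_info, user, fixed = TRUE)
  structure(
    list(
      system_text = paste(
        "You map natural-language questions about an RDF database onto the",
        "variables of a curated schema. Select variable names only from the",
        "provided list and copy condition values verbatim from the question."),
      user_text = user,
      question = question
    ),
    class = "prompt_bundle"
  )
}

default_prompt_template <- function() {
  path <- system.file("templates", "extraction_prompt.txt",
                      package = "sparqlgen")
  paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n")
}

#' Serialize an extraction result as a fenced answer block
#'
#' The inverse of [parse_extraction_output()]: emits the fenced `json` block
#' contract. `parse_extraction_output(serialize_extraction(x), schema)`
#' recovers `x`'s variables and parameters byte-exactly.
#'
#' @param result An `extraction_result` (or a list with `variables` and a
#'   `parameters` data frame).
#' @return A string containing one fenced code block.
#' @export
serialize_extraction <- function(result) {
  params <- result$parameters
  payload <- list(
    variables = as.list(as.character(result$variables)),
    parameters = if (nrow(params)) {
      lapply(seq_len(nrow(params)),
             function(i) list(params$variable[[i]], params$value[[i]]))
    } else {
      list()
    }
  )
  paste0("```json\n",
         jsonlite::toJSON(payload, auto_unbox = TRUE), "\n```\n")
}

#' Parse a model completion into a validated extraction result
#'
#' Extracts the final fenced code block from the completion, parses it as
#' JSON (`variables`: list of names; `parameters`: list of
#' `[variable, value]` pairs), and validates every variable name against the
#' schema. Unknown names are a hard error naming the offenders — no silent
#' dropping, no fuzzy matching — so model-induced errors surface instead of
#' leaking into queries. Parameter values are preserved byte-exactly.
#'
#' @param raw Non-empty completion text.
#' @param schema A `sparql_schema` to validate names against.
#' @return An object of class `extraction_result`: `variables` (character),
#'   `parameters` (data frame `variable`, `value`), `trace` (the completion
#'   text, kept verbatim), `warnings` (empty; filled by [extract_request()]).
#' @export
parse_extraction_output <- function(raw, schema) {
  stopifnot(inherits(schema, "sparql_schema"))
  if (!is.character(raw) || length(raw) != 1L || !nzchar(raw)) {
    stop("model output is empty", call. = FALSE)
  }
  m <- gregexpr("(?s)```[A-Za-z]*[ \t]*\\n(.*?)```", raw, perl = TRUE)[[1]]
  if (m[[1]] == -1L) {
    stop("no fenced answer block found in model output", call. = FALSE)
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  k <- length(starts)
  block <- substr(raw, starts[[k]], starts[[k]] + lens[[k]] - 1L)
  inner <- sub("^```[A-Za-z]*\\s*\\n", "", block)
  inner <- sub("```$", "", inner)
  payload <- tryCatch(jsonlite::fromJSON(inner, simplifyVector = FALSE),
                      error = function(e) {
                        stop("unparseable answer block: ",
                             conditionMessage(e), call. = FALSE)
                      })
  if (!is.list(payload) || is.null(payload$variables) &&
      is.null(payload$parameters)) {
    stop("answer block must be an object with 'variables' and 'parameters'",
         call. = FALSE)
  }
  variables <- vapply(payload$variables %||% list(), function(v) {
    if (!is.character(v) || length(v) != 1L) {
      stop("answer block variables must be strings", call. = FALSE)
    }
    v
  }, character(1))
  if (anyDuplicated(variables)) {
    stop("duplicate variable in answer block: ",
         paste(unique(variables[duplicated(variables)]), collapse = ", "),
         call. = FALSE)
  }
  plist <- payload$parameters %||% list()
  params <- if (length(plist)) {
    do.call(rbind, lapply(plist, function(p) {
      if (length(p) != 2L) {
        stop("each parameter in the answer block must be a ",
             "[variable, value] pair", call. = FALSE)
      }
      data.frame(variable = as.character(p[[1]]),
                 value = as.character(p[[2]]), stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(variable = character(0), value = character(0),
               stringsAsFactors = FALSE)
  }
  if (any(!nzchar(params$value))) {
    stop("parameter with empty value in answer block for variable(s): ",
         paste(params$variable[!nzchar(params$value)], collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(c(variables, params$variable)),
                     names(schema$nodes))
  if (length(unknown)) {
    stop("unknown variable name(s) in answer block: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(
    list(variables = variables, parameters = params, trace = raw,
         warnings = character(0)),
    class = "extraction_result"
  )
}

#' Warn about parameter values that were not copied verbatim
#'
#' The extraction contract asks the model to copy condition values from the
#' question text unchanged. Values that are not a verbatim (case-sensitive)
#' substring of the question are likely hallucinated edits — e.g. rewriting
#' the `=` in a reaction equation as `=>` — and each produces one warning.
#' The check is advisory: legitimate normalisation may trip it, so nothing
#' is blocked and the guard never raises. It checks against the question
#' only, never against database content.
#'
#' @param result An `extraction_result`.
#' @param question The original question text.
#' @return Character vector of warning messages (empty when all values are
#'   verbatim substrings).
#' @export
check_strict_copy <- function(result, question) {
  params <- result$parameters
  if (is.null(params) || nrow(params) == 0L) return(character(0))
  out <- character(0)
  for (i in seq_len(nrow(params))) {
    if (!grepl(params$value[[i]], question, fixed = TRUE)) {
      out <- c(out, paste0("parameter value for '", params$variable[[i]],
                           "' is not a verbatim substring of the question: \"",
                           params$value[[i]], "\""))
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Language-model client contract

#' Create a language-model client
#'
#' The extraction stage is model-agnostic: any function that maps a
#' [build_extraction_prompt()] bundle to a completion string can serve.
#' Deterministic settings (temperature 0) are the recorded default.
#'
#' @param complete_fn `function(bundle) -> string`.
#' @param model_id Identifier recorded in reports and logs.
#' @param temperature Sampling temperature metadata (no effect on the mock).
#' @return An object of class `llm_client`.
#' @export
llm_client <- function(complete_fn, model_id = "custom", temperature = 0) {
  stopifnot(is.function(complete_fn))
  structure(list(complete_fn = complete_fn, model_id = model_id,
                 temperature = temperature),
            class = "llm_client")
}

#' Deterministic mock client for offline runs and tests
#'
#' @param respond One of: a single string (returned for every prompt); a
#'   named character vector mapping question text to completions (a prompt
#'   whose question has no entry is an error); or a
#'   `function(bundle) -> string`.
#' @return An `llm_client` that is a pure function of the prompt.
#' @export
mock_llm_client <- function(respond) {
  fn <- if (is.function(respond)) {
    respond
  } else if (is.character(respond) && length(respond) == 1L &&
             is.null(names(respond))) {
    function(bundle) respond
  } else if (is.character(respond) && !is.null(names(respond))) {
    function(bundle) {
      if (!bundle$question %in% names(respond)) {
        stop(sparql_error("transport",
                          paste0("mock client has no scripted answer for: ",
                                 bundle$question)))
      }
      respond[[bundle$question]]
    }
  } else {
    stop("respond must be a string, a named character vector, or a function",
         call. = FALSE)
  }
  llm_client(fn, model_id = "mock", temperature = 0)
}

#' Send a prompt to a client
#'
#' @param client An [llm_client()].
#' @param bundle A `prompt_bundle`.
#' @return The completion string.
#' @export
llm_complete <- function(client, bundle) {
  stopifnot(inherits(client, "llm_client"), inherits(bundle, "prompt_bundle"))
  out <- client$complete_fn(bundle)
  if (!is.character(out) || length(out) != 1L) {
    stop(sparql_error("transport", "client returned a non-string completion"))
  }
  out
}

#' Run the full extraction pipeline for one question
#'
#' Composes the stages: list selectable variables, format the listing for the
#' chosen presentation mode, build the four-step prompt, call the client,
#' parse and validate the answer, and attach strict-copy warnings. With the
#' mock client the pipeline is a pure function of its inputs. The schema is
#' never mutated.
#'
#' Presentation modes: `"VwE"` — variable names, examples and explanations
#' (the default and the most accurate setting); `"VwoE"` — names and examples
#' without explanations; `"VinS"` — the raw schema document text instead of a
#' listing.
#'
#' @param question Non-empty question text.
#' @param schema A `sparql_schema`.
#' @param client An [llm_client()].
#' @param explanations Optional explanations passed to
#'   [list_selectable_variables()].
#' @param mode One of `"VwE"`, `"VwoE"`, `"VinS"`.
#' @param template Optional prompt template override.
#' @return An `extraction_result` with `warnings` filled in and the prompt
#'   bundle attached as attribute `"prompt"`.
#' @export
extract_request <- function(question, schema, client, explanations = NULL,
                            mode = c("VwE", "VwoE", "VinS"),
                            template = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(schema, "sparql_schema"))
  info <- switch(
    mode,
    VwE = format_variables_info(
      list_selectable_variables(schema, explanations),
      include_explanations = TRUE),
    VwoE = format_variables_info(
      list_selectable_variables(schema, explanations),
      include_explanations = FALSE),
    VinS = render_schema(schema)
  )
  bundle <- build_extraction_prompt(question, info, template = template)
  raw <- llm_complete(client, bundle)
  result <- parse_extraction_output(raw, schema)
  result$warnings <- check_strict_copy(result, question)
  attr(result, "prompt") <- bundle
  result
}

#' Convert an extraction result into a query request
#'
#' @param result An `extraction_result`.
#' @return A [query_request()].
#' @export
as_query_request <- function(result) {
  stopifnot(inherits(result, "extraction_result"))
  query_request(result$variables, result$parameters)
}

#' @export
print.extraction_result <- function(x, ...) {
  cat("<extraction_result>\n")
  cat("  variables:  ", paste(x$variables, collapse = ", "), "\n", sep = "")
  if (nrow(x$parameters)) {
    for (i in seq_len(nrow(x$parameters))) {
      cat("  parameter:  ", x$parameters$variable[[i]], " = \"",
          x$parameters$value[[i]], "\"\n", sep = "")
    }
  }
  for (w in x$warnings) cat("  warning:    ", w, "\n", sep = "")
  invisible(x)
}
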