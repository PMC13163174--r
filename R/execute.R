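#' Construct a result table
#'
#' A result table is the unit the execution-based metric compares: an ordered
#' list of rows, each row a finite set of cell-value strings. Column identity
#' is deliberately ignored and duplicate values within a row collapse, because
#' row similarity is defined as the Jaccard coefficient of two value sets.
#'
#' @param rows A list of character vectors (each is de-duplicated and sorted
#'   into a canonical set representation).
#' @param origin Optional label, e.g. `"G"` (ground truth) or `"Q"`
#'   (generated).
#' @return An object of class `result_table`.
#' @export
result_table <- function(rows = list(), origin = NULL) {
  rows <- lapply(rows, function(r) {
    r <- as.character(r)
    if (anyNA(r)) stop("result cells must be non-missing strings", call. = FALSE)
    sort(unique(r), method = "radix")
  })
  structure(list(rows = rows, origin = origin), class = "result_table")
}

#' @export
print.result_table <- function(x, n = 10L, ...) {
  cat("<result_table> ", length(x$rows), " rows",
      if (!is.null(x$origin)) paste0(" (", x$origin, ")"), "\n", sep = "")
  for (i in seq_len(min(n, length(x$rows)))) {
    cat("  {", paste(x$rows[[i]], collapse = ", "), "}\n", sep = "")
  }
  if (length(x$rows) > n) cat("  ...\n")
  invisible(x)
}

#' Read / write result tables as tab-separated text
#'
#' One row per line, cells tab-separated. An empty file is an empty table.
#'
#' @param path File path.
#' @param origin Optional origin label attached on read.
#' @return `read_result_table` returns a `result_table`; `write_result_table`
#'   returns `path` invisibly.
#' @export
read_result_table <- function(path, origin = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  result_table(strsplit(lines, "\t", fixed = TRUE), origin = origin)
}

#' @rdname read_result_table
#' @param table A `result_table`.
#' @export
write_result_table <- function(table, path) {
  stopifnot(inherits(table, "result_table"))
  writeLines(vapply(table$rows, paste, character(1), collapse = "\t"),
             con = path, useBytes = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# SPARQL subset parser + in-process evaluator.
#
# The builder emits exactly: PREFIX lines, SELECT DISTINCT ?v ..., and a
# WHERE block of triple patterns plus VALUES blocks. This evaluator covers
# that dialect (and nothing more) so the whole question-to-answer loop runs
# offline over fixture graphs.

parse_sparql_subset <- function(query_text) {
  toks <- tokenize_sparql(query_text)
  i <- 1L
  n <- length(toks)
  take <- function() {
    if (i > n) stop("unexpected end of query", call. = FALSE)
    tk <- toks[[i]]
    i <<- i + 1L
    tk
  }
  peek <- function() if (i <= n) toks[[i]] else NA_character_

  prefixes <- character(0)
  while (identical(toupper(peek()), "PREFIX")) {
    take()
    lbl <- take()
    if (!grepl(":$", lbl)) stop("malformed PREFIX declaration", call. = FALSE)
    iri <- take()
    if (!startsWith(iri, "<")) stop("PREFIX namespace must be an <IRI>",
                                    call. = FALSE)
    prefixes[sub(":$", "", lbl)] <- substr(iri, 2L, nchar(iri) - 1L)
  }
  if (!identical(toupper(take()), "SELECT")) {
    stop("only SELECT queries are supported", call. = FALSE)
  }
  distinct <- FALSE
  if (identical(toupper(peek()), "DISTINCT")) {
    distinct <- TRUE
    take()
  }
  select_vars <- character(0)
  star <- FALSE
  while (!is.na(peek()) && !identical(toupper(peek()), "WHERE")) {
    tk <- take()
    if (tk == "*") star <- TRUE
    else if (startsWith(tk, "?")) select_vars <- c(select_vars, substring(tk, 2L))
    else stop("unexpected token '", tk, "' in SELECT clause", call. = FALSE)
  }
  if (is.na(peek())) stop("missing WHERE clause", call. = FALSE)
  take()  # WHERE
  if (!identical(take(), "{")) stop("expected '{' after WHERE", call. = FALSE)

  resolve_tok <- function(tk) {
    if (startsWith(tk, "?")) return(tk)
    if (startsWith(tk, "<") || startsWith(tk, "_:") || startsWith(tk, "\"")) {
      return(tk)
    }
    if (tk == "a") return(RDF_TYPE)
    resolve_term(tk, prefixes)
  }

  patterns <- list()
  values <- list()
  repeat {
    tk <- take()
    if (tk == "}") break
    if (identical(toupper(tk), "VALUES")) {
      v <- take()
      if (!startsWith(v, "?")) stop("VALUES must bind a variable", call. = FALSE)
      if (!identical(take(), "{")) stop("expected '{' after VALUES variable",
                                        call. = FALSE)
      terms <- character(0)
      repeat {
        t2 <- take()
        if (t2 == "}") break
        terms <- c(terms, resolve_tok(t2))
      }
      values[[length(values) + 1L]] <- list(variable = substring(v, 2L),
                                            terms = terms)
    } else {
      s <- resolve_tok(tk)
      p <- resolve_tok(take())
      o <- resolve_tok(take())
      dot <- take()
      if (dot != "." && dot != "}") {
        stop("expected '.' after triple pattern", call. = FALSE)
      }
      patterns[[length(patterns) + 1L]] <- c(s, p, o)
      if (dot == "}") break
    }
  }
  list(prefixes = prefixes, select_vars = select_vars, star = star,
       distinct = distinct, patterns = patterns, values = values)
}

tokenize_sparql <- function(text) {
  chars <- strsplit(paste(text, collapse = "\n"), "", fixed = TRUE)[[1]]
  toks <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[[i]]
    if (ch %in% c(" ", "\t", "\n", "\r")) {
      i <- i + 1L
    } else if (ch == "#") {
      while (i <= n && chars[[i]] != "\n") i <- i + 1L
    } else if (ch == "<") {
      j <- i + 1L
      while (j <= n && chars[[j]] != ">") j <- j + 1L
      if (j > n) stop("unterminated IRI in query", call. = FALSE)
      toks <- c(toks, paste0(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "\"") {
      j <- i + 1L
      buf <- "\""
      while (j <= n) {
        cj <- chars[[j]]
        if (cj == "\\" && j < n) {
          buf <- paste0(buf, cj, chars[[j + 1L]])
          j <- j + 2L
        } else if (cj == "\"") {
          buf <- paste0(buf, "\"")
          j <- j + 1L
          break
        } else {
          buf <- paste0(buf, cj)
          j <- j + 1L
        }
      }
      toks <- c(toks, buf)
      i <- j
    } else if (ch %in% c("{", "}", "*")) {
      toks <- c(toks, ch)
      i <- i + 1L
    } else if (ch == ".") {
      toks <- c(toks, ".")
      i <- i + 1L
    } else {
      j <- i
      while (j <= n && !chars[[j]] %in% c(" ", "\t", "\n", "\r", "{", "}",
                                          "\"", "<", "#")) {
        j <- j + 1L
      }
      word <- paste0(chars[i:(j - 1L)], collapse = "")
      if (grepl("\\.$", word) && nchar(word) > 1L) {
        toks <- c(toks, sub("\\.$", "", word), ".")
      } else {
        toks <- c(toks, word)
      }
      i <- j
    }
  }
  toks
}

# Nested-loop basic-graph-pattern join; fine at fixture scale and easy to
# audit. Solutions are kept as a list of named character vectors.
evaluate_bgp <- function(patterns, triples) {
  sols <- list(stats::setNames(character(0), character(0)))
  for (pat in patterns) {
    nxt <- list()
    cand <- triples
    for (k in 1:3) {  # pre-filter on constant positions
      if (!startsWith(pat[[k]], "?")) {
        cand <- cand[cand[[k]] == pat[[k]], , drop = FALSE]
      }
    }
    if (nrow(cand) == 0L) return(list())
    vars <- c(s = pat[[1]], p = pat[[2]], o = pat[[3]])
    vars <- vars[startsWith(vars, "?")]
    for (sol in sols) {
      for (r in seq_len(nrow(cand))) {
        ok <- TRUE
        ext <- sol
        for (pos in names(vars)) {
          vname <- substring(vars[[pos]], 2L)
          val <- cand[[pos]][[r]]
          if (vname %in% names(ext)) {
            if (!identical(ext[[vname]], val)) {
              ok <- FALSE
              break
            }
          } else {
            ext[vname] <- val
          }
        }
        if (ok) nxt[[length(nxt) + 1L]] <- ext
      }
    }
    sols <- nxt
    if (length(sols) == 0L) return(list())
  }
  sols
}

solutions_to_table <- function(sols, select_vars, star, distinct,
                               origin = NULL) {
  rows <- list()
  for (sol in sols) {
    vars <- if (star) names(sol) else select_vars
    bound <- intersect(vars, names(sol))
    rows[[length(rows) + 1L]] <- unname(sol[bound])
  }
  # normalize all cells with one per-table blank-label sequence
  flat <- unlist(rows, use.names = FALSE)
  if (length(flat)) {
    norm <- normalize_cells(flat)
    idx <- 0L
    rows <- lapply(rows, function(r) {
      out <- norm[idx + seq_along(r)]
      idx <<- idx + length(r)
      out
    })
  }
  tab <- result_table(rows, origin = origin)
  if (distinct) {
    keys <- vapply(tab$rows, paste, character(1), collapse = "\r")
    tab$rows <- tab$rows[!duplicated(keys)]
  }
  tab
}

#' Execute a SPARQL query over a local Turtle graph
#'
#' Runs the query in-process against a graph parsed by [parse_turtle()],
#' covering the dialect emitted by [build_query()] (basic graph patterns,
#' VALUES blocks, `SELECT DISTINCT`). Deterministic: solution order follows
#' pattern order and graph statement order.
#'
#' @param query_text SPARQL text (string), typically `build_query(...)$text`.
#' @param graph_source Turtle text, a file path to a Turtle document, or an
#'   `rdf_graph`.
#' @param origin Optional origin label for the returned table.
#' @return A [result_table()] with cells normalised (full IRI strings; bare
#'   literal lexical forms; stable per-table blank labels).
#' @export
execute_local <- function(query_text, graph_source, origin = NULL) {
  graph <- if (inherits(graph_source, "rdf_graph")) {
    graph_source
  } else if (length(graph_source) == 1L && !grepl("\n", graph_source) &&
             file.exists(graph_source)) {
    parse_turtle(paste(readLines(graph_source, encoding = "UTF-8",
                                 warn = FALSE), collapse = "\n"))
  } else {
    parse_turtle(graph_source)
  }
  q <- parse_sparql_subset(query_text)
  sols <- evaluate_bgp(q$patterns, graph$triples)
  for (vb in q$values) {
    sols <- Filter(function(sol) {
      vb$variable %in% names(sol) && sol[[vb$variable]] %in% vb$terms
    }, sols)
  }
  solutions_to_table(sols, q$select_vars, q$star, q$distinct, origin = origin)
}

# ---------------------------------------------------------------------------
# Remote execution (SPARQL Protocol over HTTP)

#' Configure a SPARQL endpoint
#'
#' @param url Endpoint URL (http/https).
#' @param timeout Request timeout in seconds (> 0).
#' @param limit Optional row cap appended as a warning threshold: when the
#'   endpoint returns exactly `limit` rows a truncation warning is raised.
#' @param headers Optional named character vector of extra HTTP headers.
#' @param transport Optional function `(endpoint, query_text) ->
#'   list(status, content_type, body)`; injectable for offline tests. The
#'   default posts the query with the `curl` package.
#' @return An object of class `endpoint_config`.
#' @export
endpoint_config <- function(url, timeout = 60, limit = NULL, headers = NULL,
                            transport = NULL) {
  if (!grepl("^https?://[^[:space:]]+$", url)) {
    stop("endpoint url must be an http(s) IRI", call. = FALSE)
  }
  stopifnot(is.numeric(timeout), timeout > 0)
  if (!is.null(limit)) stopifnot(limit >= 1)
  structure(list(url = url, timeout = timeout, limit = limit,
                 headers = headers, transport = transport),
            class = "endpoint_config")
}

default_transport <- function(endpoint, query_text) {
  if (!requireNamespace("curl", quietly = TRUE)) {
    stop("remote execution needs the 'curl' package (or an injected ",
         "transport)", call. = FALSE)
  }
  h <- curl::new_handle(timeout = endpoint$timeout)
  hdrs <- c(Accept = "application/sparql-results+json",
            `Content-Type` = "application/x-www-form-urlencoded",
            endpoint$headers)
  do.call(curl::handle_setheaders, c(list(h), as.list(hdrs)))
  curl::handle_setopt(h, postfields = paste0("query=",
                                             utils::URLencode(query_text,
                                                              reserved = TRUE)))
  resp <- tryCatch(curl::curl_fetch_memory(endpoint$url, handle = h),
                   error = function(e) {
                     stop(sparql_error("transport",
                                       conditionMessage(e)))
                   })
  list(status = resp$status_code,
       content_type = resp$type %||% "",
       body = rawToChar(resp$content))
}

sparql_error <- function(kind, message) {
  structure(class = c(paste0("sparql_", kind, "_error"), "error", "condition"),
            list(message = message, call = NULL))
}

#' Execute a SPARQL query against a remote endpoint
#'
#' Issues the query per the SPARQL Protocol and parses the standard results
#' serialization (JSON; XML fallback) into a [result_table()] under the same
#' cell-normalisation policy as [execute_local()], so local and remote
#' execution of one graph agree. Transport failures, HTTP error statuses and
#' malformed result documents raise distinct condition classes
#' (`sparql_transport_error`, `sparql_http_error`, `sparql_results_error`).
#'
#' @param query_text SPARQL text.
#' @param endpoint An [endpoint_config()].
#' @param origin Optional origin label for the returned table.
#' @return A [result_table()]; solution order is preserved.
#' @export
execute_remote <- function(query_text, endpoint, origin = NULL) {
  stopifnot(inherits(endpoint, "endpoint_config"), nzchar(query_text))
  transport <- endpoint$transport %||% default_transport
  resp <- transport(endpoint, query_text)
  if (is.null(resp$status) || resp$status >= 400 || resp$status == 0) {
    stop(sparql_error("http", paste0("endpoint returned HTTP status ",
                                     resp$status)))
  }
  ct <- tolower(resp$content_type %||% "")
  bindings <- if (grepl("xml", ct)) {
    parse_results_xml(resp$body)
  } else {
    parse_results_json(resp$body)
  }
  tab <- bindings_to_table(bindings, origin = origin)
  if (!is.null(endpoint$limit) && length(tab$rows) >= endpoint$limit) {
    warning("endpoint returned ", length(tab$rows),
            " rows, at the configured limit (", endpoint$limit,
            "); results may be truncated", call. = FALSE)
  }
  tab
}

# Both parsers return a list of binding sets: named lists of term records
# (list(kind, value, datatype, lang)).
parse_results_json <- function(body) {
  doc <- tryCatch(jsonlite::fromJSON(body, simplifyVector = FALSE),
                  error = function(e) {
                    stop(sparql_error("results",
                                      paste0("malformed results JSON: ",
                                             conditionMessage(e))))
                  })
  if (is.null(doc$results$bindings)) {
    stop(sparql_error("results", "results JSON lacks results.bindings"))
  }
  lapply(doc$results$bindings, function(b) {
    lapply(b, function(cell) {
      list(kind = switch(cell$type %||% "literal",
                         uri = "iri", bnode = "blank", "literal"),
           value = as.character(cell$value),
           datatype = cell$datatype %||% NULL,
           lang = cell$`xml:lang` %||% NULL)
    })
  })
}

parse_results_xml <- function(body) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop(sparql_error("results", "XML results need the 'xml2' package"))
  }
  doc <- tryCatch(xml2::read_xml(body),
                  error = function(e) {
                    stop(sparql_error("results",
                                      paste0("malformed results XML: ",
                                             conditionMessage(e))))
                  })
  results <- xml2::xml_find_all(doc, ".//*[local-name()='result']")
  lapply(results, function(res) {
    bnodes <- xml2::xml_find_all(res, "./*[local-name()='binding']")
    out <- list()
    for (b in bnodes) {
      nm <- xml2::xml_attr(b, "name")
      child <- xml2::xml_child(b)
      tag <- xml2::xml_name(child)
      out[[nm]] <- list(
        kind = switch(tag, uri = "iri", bnode = "blank", "literal"),
        value = xml2::xml_text(child),
        datatype = xml2::xml_attr(child, "datatype"),
        lang = xml2::xml_attr(child, "lang")
      )
      if (is.na(out[[nm]]$datatype %||% NA)) out[[nm]]$datatype <- NULL
      if (is.na(out[[nm]]$lang %||% NA)) out[[nm]]$lang <- NULL
    }
    out
  })
}

bindings_to_table <- function(bindings, origin = NULL) {
  rows <- lapply(bindings, function(b) {
    vapply(b, function(cell) {
      switch(cell$kind,
             iri = term_iri(cell$value),
             blank = term_blank(cell$value),
             term_literal(cell$value,
                          datatype = if (!is.null(cell$datatype))
                            term_iri(cell$datatype),
                          lang = cell$lang))
    }, character(1), USE.NAMES = FALSE)
  })
  flat <- unlist(rows, use.names = FALSE)
  if (length(flat)) {
    norm <- normalize_cells(flat)
    idx <- 0L
    rows <- lapply(rows, function(r) {
      out <- norm[idx + seq_along(r)]
      idx <<- idx + length(r)
      out
    })
  }
  result_table(rows, origin = origin)
}
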