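#' Construct a query request
#'
#' A request is the interface between the extraction stage and the query
#' builder: `variables` are the items to retrieve (they become the SELECT
#' clause) and `parameters` are (variable, value) pairs that constrain the
#' query through VALUES blocks.
#'
#' @param variables Character vector of schema variable names to retrieve
#'   (may be empty if at least one parameter is given).
#' @param parameters Parameter bindings: a list of `c(name, value)` pairs, a
#'   named character vector, or a two-column data frame (`variable`, `value`).
#'   Repeated names are allowed; repeated values of one variable form a
#'   disjunction.
#' @return An object of class `query_request` with elements `variables` and
#'   `parameters` (data frame `variable`, `value`).
#' @examples
#' query_request("uniprot_citation",
#'               parameters = list(c("uniprot_taxonomy", "taxonomy:9606")))
#' @export
query_request <- function(variables = character(0), parameters = list()) {
  variables <- as.character(variables)
  params <- normalize_parameters(parameters)
  if (length(variables) == 0L && nrow(params) == 0L) {
    stop("empty request: need at least one variable or parameter",
         call. = FALSE)
  }
  if (anyDuplicated(variables)) {
    stop("duplicate names in request variables: ",
         paste(unique(variables[duplicated(variables)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(variables = variables, parameters = params),
            class = "query_request")
}

normalize_parameters <- function(parameters) {
  if (is.data.frame(parameters)) {
    stopifnot(all(c("variable", "value") %in% names(parameters)))
    return(data.frame(variable = as.character(parameters$variable),
                      value = as.character(parameters$value),
                      stringsAsFactors = FALSE))
  }
  if (is.character(parameters) && !is.null(names(parameters))) {
    return(data.frame(variable = names(parameters),
                      value = unname(parameters), stringsAsFactors = FALSE))
  }
  stopifnot(is.list(parameters))
  if (length(parameters) == 0L) {
    return(data.frame(variable = character(0), value = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(parameters, function(p) {
    if (length(p) != 2L) {
      stop("each parameter must be a (variable, value) pair", call. = FALSE)
    }
    data.frame(variable = as.character(p[[1]]), value = as.character(p[[2]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Triple patterns needed to reach a set of variables
#'
#' Walks the schema tree from each subject-root down to every needed variable
#' and returns the union of the traversed edges, plus one `rdf:type` pattern
#' per root whose subtree contributes a needed variable. Connector variables
#' appear as intermediate variables wherever a path passes through them.
#'
#' @param schema A `sparql_schema`.
#' @param needed Character vector of variable names (non-empty).
#' @return A data frame of patterns with columns `subject`, `predicate`,
#'   `object` — `subject` and variable objects are `?name` strings, constant
#'   objects are prefixed names; order is root-then-document order and
#'   deterministic.
#' @export
resolve_triple_patterns <- function(schema, needed) {
  stopifnot(inherits(schema, "sparql_schema"))
  needed <- unique(as.character(needed))
  if (length(needed) == 0L) stop("'needed' must be non-empty", call. = FALSE)
  unknown <- setdiff(needed, names(schema$nodes))
  if (length(unknown)) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  roots_hit <- unique(vapply(needed, function(v) schema$nodes[[v]]$root,
                             character(1)))
  roots_hit <- schema$roots[schema$roots %in% roots_hit]

  edge_key <- function(e) paste(e$parent, e$predicate, e$child, sep = "\r")
  needed_edges <- character(0)
  for (v in needed) {
    p <- path_to_root(schema, v)
    if (nrow(p)) needed_edges <- c(needed_edges, edge_key(p))
  }

  pats <- list()
  for (root in roots_hit) {
    for (tp in schema$nodes[[root]]$rdf_types) {
      pats[[length(pats) + 1L]] <- data.frame(
        subject = paste0("?", root), predicate = "a", object = tp,
        stringsAsFactors = FALSE)
    }
    in_root <- vapply(schema$edges$child,
                      function(ch) schema$nodes[[ch]]$root == root, logical(1))
    root_edges <- schema$edges[in_root, , drop = FALSE]
    for (i in seq_len(nrow(root_edges))) {
      e <- root_edges[i, , drop = FALSE]
      if (edge_key(e) %in% needed_edges) {
        pats[[length(pats) + 1L]] <- data.frame(
          subject = paste0("?", e$parent), predicate = e$predicate,
          object = paste0("?", e$child), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, pats)
}

#' Build a SPARQL SELECT query from a schema and a request
#'
#' Requested variables become the SELECT clause (in request order); the WHERE
#' clause contains the property paths from each relevant subject-root to every
#' requested or constrained variable, plus one VALUES block per constrained
#' variable. Constraints always use VALUES, never FILTER, so the generated
#' dialect stays simple and auditable. `DISTINCT` is always emitted so that
#' result-table comparison does not depend on store internals.
#'
#' Parameter values are typed by a fixed rule: a value of the form
#' `prefix:local` with a declared prefix is emitted as a prefixed name; a
#' value already wrapped in double quotes is emitted verbatim as a literal;
#' anything else becomes a plain literal.
#'
#' @param schema A `sparql_schema`.
#' @param request A [query_request()].
#' @return An object of class `sparql_query`: list with `prefixes` (named
#'   character, sorted by label, restricted to used prefixes), `select_vars`,
#'   `patterns` (data frame as in [resolve_triple_patterns()]), `values`
#'   (list of `list(variable, terms)`), and `text`, the rendered query.
#' @examples
#' sch <- parse_schema("
#' prefixes:
#'   ex: <http://example.org/>
#' model:
#'   - Entry ex:e1:
#'       - a: ex:Entry
#'       - ex:label:
#'           entry_label: something
#' ")
#' q <- build_query(sch, query_request("entry_label"))
#' cat(q$text)
#' @export
build_query <- function(schema, request) {
  stopifnot(inherits(schema, "sparql_schema"),
            inherits(request, "query_request"))
  all_names <- c(request$variables, request$parameters$variable)
  unknown <- setdiff(all_names, names(schema$nodes))
  if (length(unknown)) {
    stop("unknown variable(s) in request: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  needed <- unique(all_names)
  patterns <- resolve_triple_patterns(schema, needed)

  values <- list()
  for (v in unique(request$parameters$variable)) {
    vals <- request$parameters$value[request$parameters$variable == v]
    terms <- vapply(vals, function(val) {
      parameter_term(val, schema$prefixes)$render
    }, character(1), USE.NAMES = FALSE)
    values[[length(values) + 1L]] <- list(variable = v, terms = terms)
  }

  used <- character(0)
  for (x in c(patterns$predicate, patterns$object)) {
    lbl <- prefix_label_of(x)
    if (!is.na(lbl) && !startsWith(x, "?")) used <- c(used, lbl)
  }
  for (vb in values) {
    for (tm in vb$terms) {
      lbl <- prefix_label_of(tm)
      if (!is.na(lbl) && !startsWith(tm, "\"")) used <- c(used, lbl)
    }
  }
  used <- sort(intersect(names(schema$prefixes), unique(used)))
  prefixes <- schema$prefixes[used]

  query <- structure(
    list(prefixes = prefixes, select_vars = request$variables,
         patterns = patterns, values = values, text = NULL),
    class = "sparql_query"
  )
  query$text <- render_sparql(query)
  query
}

#' Render a structured query to deterministic SPARQL text
#'
#' Layout is fixed: PREFIX declarations, a blank line (only when prefixes
#' exist), a `SELECT DISTINCT` line, and a WHERE block with one triple
#' pattern per line terminated by `" ."`, VALUES blocks last. Output is
#' byte-identical across calls and platforms.
#'
#' @param query A `sparql_query` (the `text` element is ignored and
#'   recomputed).
#' @return A single string.
#' @export
render_sparql <- function(query) {
  stopifnot(inherits(query, "sparql_query"))
  lines <- character(0)
  for (lbl in names(query$prefixes)) {
    lines <- c(lines, paste0("PREFIX ", lbl, ": <", query$prefixes[[lbl]], ">"))
  }
  if (length(lines)) lines <- c(lines, "")
  sel <- if (length(query$select_vars)) {
    paste0("?", query$select_vars, collapse = " ")
  } else {
    "*"
  }
  lines <- c(lines, paste0("SELECT DISTINCT ", sel), "WHERE {")
  pats <- query$patterns
  for (i in seq_len(nrow(pats))) {
    lines <- c(lines, paste0("  ", pats$subject[[i]], " ", pats$predicate[[i]],
                             " ", pats$object[[i]], " ."))
  }
  for (vb in query$values) {
    lines <- c(lines, paste0("  VALUES ?", vb$variable, " { ",
                             paste(vb$terms, collapse = " "), " }"))
  }
  lines <- c(lines, "}")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @export
print.sparql_query <- function(x, ...) {
  cat(x$text)
  invisible(x)
}

#' Export the structured form of a query as a plain list
#'
#' Useful for machine inspection (e.g. `jsonlite::toJSON`).
#'
#' @param query A `sparql_query`.
#' @return A list with `prefixes`, `select_vars`, `patterns`, `values`, `text`.
#' @export
query_record <- function(query) {
  stopifnot(inherits(query, "sparql_query"))
  list(
    prefixes = as.list(query$prefixes),
    select_vars = query$select_vars,
    patterns = query$patterns,
    values = lapply(query$values, function(v)
      list(variable = v$variable, terms = v$terms)),
    text = query$text
  )
}
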