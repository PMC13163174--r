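#' Parse a YAML database schema into a validated tree model
#'
#' A schema describes the RDF model of a database as a forest of named
#' variables: each database entry class is a subject-root node carrying one or
#' more `rdf:type`s, and its attributes are child nodes reached through
#' predicates. Human-readable variable names, example values and curated
#' explanations make the model usable both by people and by the language-model
#' extraction stage, while the query builder uses the tree to derive property
#' paths.
#'
#' The accepted YAML dialect (a documented compatible subset of the upstream
#' schema format) is one document with top-level keys:
#' \describe{
#'   \item{`name`}{dataset label (optional, defaults to `""`).}
#'   \item{`prefixes`}{mapping from prefix label to namespace IRI, with or
#'     without angle brackets. The label `a` is reserved.}
#'   \item{`model`}{a list of subject blocks. Each block is a one-key mapping
#'     whose key is `"<VariableName> <example>"` (example optional) and whose
#'     value is a list of entries: `a: <type>` declares an `rdf:type`
#'     (subject-roots only); `explanation: <text>` and `selectable: true`
#'     annotate the current node; any other key is a predicate. A predicate
#'     mapping to `{<variable>: <example>}` (plus optional `explanation` /
#'     `selectable`) declares a leaf object; a predicate mapping to a list
#'     whose first element is `{<variable>: <example>}` declares a subtree,
#'     whose remaining elements are entries of that child node.}
#' }
#' A non-root node with children and no explicit `selectable: true` flag is a
#' connector: it links property paths but is hidden from user-facing variable
#' listings. Example values are opaque lexical forms and are never validated
#' against the prefix map.
#'
#' @param yaml_text Schema document as a single string (or a character vector
#'   of lines).
#' @return An object of class `sparql_schema`: a list with elements `name`,
#'   `prefixes` (named character), `nodes` (named list, document order),
#'   `edges` (data frame with columns `parent`, `predicate`, `child`) and
#'   `roots` (character vector of subject-root names).
#' @examples
#' sch <- parse_schema("
#' name: demo
#' prefixes:
#'   ex: <http://example.org/>
#' model:
#'   - Entry ex:e1:
#'       - a: ex:Entry
#'       - ex:label:
#'           entry_label: something
#' ")
#' sch$roots
#' @seealso [read_schema()], [render_schema()], [list_selectable_variables()],
#'   [path_to_root()]
#' @export
parse_schema <- function(yaml_text) {
  if (length(yaml_text) > 1L) yaml_text <- paste(yaml_text, collapse = "\n")
  doc <- yaml::yaml.load(yaml_text)
  if (!is.list(doc)) stop("schema document must be a YAML mapping", call. = FALSE)
  extra <- setdiff(names(doc), c("name", "prefixes", "model"))
  if (length(extra)) {
    stop("unsupported top-level schema keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  name <- as.character(doc$name %||% "")
  prefixes <- parse_prefix_block(doc$prefixes)
  if (is.null(doc$model) || !is.list(doc$model) || length(doc$model) == 0L) {
    stop("schema must declare a non-empty 'model' list", call. = FALSE)
  }

  state <- new.env(parent = emptyenv())
  state$nodes <- list()
  state$edges <- list()
  state$roots <- character(0)

  for (block in doc$model) {
    if (!is.list(block) || length(block) != 1L || is.null(names(block))) {
      stop("each model item must be a one-key mapping of a subject header",
           call. = FALSE)
    }
    header <- names(block)[[1]]
    parsed <- parse_subject_header(header)
    add_schema_node(state, parsed$name, parsed$example, root = parsed$name)
    state$roots <- c(state$roots, parsed$name)
    parse_node_entries(state, parsed$name, block[[1]], prefixes,
                       is_root = TRUE, root = parsed$name)
  }

  nodes <- state$nodes
  roots <- state$roots
  for (r in roots) {
    if (length(nodes[[r]]$rdf_types) == 0L) {
      stop("subject-root '", r, "' declares no rdf:type ('a:' entry)",
           call. = FALSE)
    }
  }
  edges <- if (length(state$edges)) {
    do.call(rbind, lapply(state$edges, function(e) {
      data.frame(parent = e$parent, predicate = e$predicate, child = e$child,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(parent = character(0), predicate = character(0),
               child = character(0), stringsAsFactors = FALSE)
  }

  # classify: root / connector (has children, not flagged) / object
  has_child <- unique(edges$parent)
  for (nm in names(nodes)) {
    node <- nodes[[nm]]
    nodes[[nm]]$kind <- if (nm %in% roots) {
      "subject-root"
    } else if (nm %in% has_child && !isTRUE(node$selectable)) {
      "connector"
    } else {
      "object"
    }
  }

  schema <- structure(
    list(name = name, prefixes = prefixes, nodes = nodes, edges = edges,
         roots = roots),
    class = "sparql_schema"
  )
  stopifnot(nrow(schema$edges) + length(schema$roots) ==
              length(schema$nodes))
  schema
}

#' Read a schema from a YAML file
#'
#' @param path Path to a schema document in the dialect of [parse_schema()].
#' @return A `sparql_schema`.
#' @export
read_schema <- function(path) {
  parse_schema(paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                     collapse = "\n"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_prefix_block <- function(block) {
  if (is.null(block)) return(stats::setNames(character(0), character(0)))
  if (!is.list(block) || is.null(names(block))) {
    stop("'prefixes' must be a mapping of label to namespace IRI",
         call. = FALSE)
  }
  out <- vapply(block, function(v) {
    v <- as.character(v)
    sub("^<(.*)>$", "\\1", v)
  }, character(1))
  validate_prefix_map(out)
  out
}

parse_subject_header <- function(header) {
  header <- trimws(header)
  parts <- regmatches(header, regexec("^(\\S+)(\\s+(.*))?$", header))[[1]]
  if (length(parts) < 2L || !is_identifier(parts[[2]])) {
    stop("malformed subject header '", header,
         "': expected \"<VariableName> <example>\" with an identifier name",
         call. = FALSE)
  }
  list(name = parts[[2]],
       example = if (length(parts) >= 4L) trimws(parts[[4]]) else "")
}

RESERVED_NODE_KEYS <- c("a", "explanation", "selectable")

add_schema_node <- function(state, name, example, root) {
  if (!is_identifier(name) || name %in% RESERVED_NODE_KEYS) {
    stop("invalid variable name '", name,
         "': must be an identifier (letters, digits, underscore; not ",
         "starting with a digit) and not a reserved key", call. = FALSE)
  }
  if (name %in% names(state$nodes)) {
    stop("duplicate variable name '", name,
         "' (names must be unique; a reused name would give the tree a ",
         "second parent)", call. = FALSE)
  }
  state$nodes[[name]] <- list(
    name = name,
    example = as.character(example %||% ""),
    rdf_types = character(0),
    explanation = "",
    selectable = FALSE,
    root = root
  )
}

parse_node_entries <- function(state, node_name, entries, prefixes,
                               is_root, root) {
  if (is.null(entries)) entries <- list()
  if (!is.list(entries)) {
    stop("entries of '", node_name, "' must form a YAML list", call. = FALSE)
  }
  for (entry in entries) {
    if (!is.list(entry) || length(entry) != 1L || is.null(names(entry))) {
      stop("each entry under '", node_name,
           "' must be a one-key mapping", call. = FALSE)
    }
    key <- names(entry)[[1]]
    value <- entry[[1]]
    if (key == "a") {
      if (!is_root) {
        stop("rdf:type ('a:') may only be declared on a subject-root, ",
             "found on '", node_name, "'", call. = FALSE)
      }
      types <- as.character(unlist(value))
      for (tp in types) resolve_term(tp, prefixes)  # fail fast on bad prefix
      state$nodes[[node_name]]$rdf_types <-
        c(state$nodes[[node_name]]$rdf_types, types)
    } else if (key == "explanation") {
      state$nodes[[node_name]]$explanation <- as.character(value %||% "")
    } else if (key == "selectable") {
      state$nodes[[node_name]]$selectable <- isTRUE(value)
    } else {
      resolve_term(key, prefixes)  # predicate must resolve
      parse_child(state, node_name, key, value, prefixes, root)
    }
  }
}

parse_child <- function(state, parent, predicate, value, prefixes, root) {
  if (is.list(value) && is.null(names(value))) {
    # subtree: first element names the child node, rest are its entries
    if (length(value) == 0L || !is.list(value[[1]]) ||
        length(value[[1]]) != 1L || is.null(names(value[[1]]))) {
      stop("subtree under predicate '", predicate, "' of '", parent,
           "' must start with a one-key '<variable>: <example>' mapping",
           call. = FALSE)
    }
    child <- names(value[[1]])[[1]]
    add_schema_node(state, child, value[[1]][[1]], root = root)
    state$edges[[length(state$edges) + 1L]] <-
      list(parent = parent, predicate = predicate, child = child)
    parse_node_entries(state, child, value[-1], prefixes,
                       is_root = FALSE, root = root)
  } else if (is.list(value) && !is.null(names(value))) {
    # leaf object, optionally annotated
    ann <- intersect(names(value), c("explanation", "selectable"))
    core <- setdiff(names(value), ann)
    if (length(core) != 1L) {
      stop("leaf under predicate '", predicate, "' of '", parent,
           "' must have exactly one '<variable>: <example>' key", call. = FALSE)
    }
    child <- core
    add_schema_node(state, child, value[[child]], root = root)
    state$edges[[length(state$edges) + 1L]] <-
      list(parent = parent, predicate = predicate, child = child)
    if ("explanation" %in% ann) {
      state$nodes[[child]]$explanation <- as.character(value$explanation %||% "")
    }
    if ("selectable" %in% ann) {
      state$nodes[[child]]$selectable <- isTRUE(value$selectable)
    }
  } else {
    stop("value under predicate '", predicate, "' of '", parent,
         "' must be a '<variable>: <example>' mapping or a subtree list",
         call. = FALSE)
  }
}

#' Serialize a schema back to its canonical YAML form
#'
#' Emits the dialect accepted by [parse_schema()] with two-space indentation.
#' `parse_schema(render_schema(s))` is structurally the identity.
#'
#' @param schema A `sparql_schema`.
#' @return A single string of YAML.
#' @export
render_schema <- function(schema) {
  stopifnot(inherits(schema, "sparql_schema"))
  out <- c(paste0("name: ", yaml_scalar(schema$name)))
  if (length(schema$prefixes)) {
    out <- c(out, "prefixes:")
    for (lbl in names(schema$prefixes)) {
      out <- c(out, paste0("  ", lbl, ": <", schema$prefixes[[lbl]], ">"))
    }
  }
  out <- c(out, "model:")
  for (root in schema$roots) {
    node <- schema$nodes[[root]]
    header <- if (nzchar(node$example)) {
      paste(root, node$example)
    } else {
      root
    }
    out <- c(out, paste0("  - ", yaml_scalar(header, key = TRUE), ":"))
    out <- c(out, render_node_entries(schema, root, indent = 6L,
                                      is_root = TRUE))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

render_node_entries <- function(schema, name, indent, is_root) {
  pad <- strrep(" ", indent)
  node <- schema$nodes[[name]]
  out <- character(0)
  if (is_root) {
    for (tp in node$rdf_types) {
      out <- c(out, paste0(pad, "- a: ", yaml_scalar(tp)))
    }
  }
  if (nzchar(node$explanation)) {
    out <- c(out, paste0(pad, "- explanation: ", yaml_scalar(node$explanation)))
  }
  if (isTRUE(node$selectable)) {
    out <- c(out, paste0(pad, "- selectable: true"))
  }
  kids <- schema$edges[schema$edges$parent == name, , drop = FALSE]
  for (i in seq_len(nrow(kids))) {
    child <- kids$child[[i]]
    cn <- schema$nodes[[child]]
    child_has_kids <- child %in% schema$edges$parent
    out <- c(out, paste0(pad, "- ", yaml_scalar(kids$predicate[[i]], key = TRUE), ":"))
    if (child_has_kids) {
      out <- c(out,
               paste0(pad, "    - ", yaml_scalar(child, key = TRUE), ": ",
                      yaml_scalar(cn$example)),
               render_node_entries(schema, child, indent + 4L, is_root = FALSE))
    } else {
      out <- c(out, paste0(pad, "    ", yaml_scalar(child, key = TRUE), ": ",
                           yaml_scalar(cn$example)))
      if (nzchar(cn$explanation)) {
        out <- c(out, paste0(pad, "    explanation: ",
                             yaml_scalar(cn$explanation)))
      }
      if (isTRUE(cn$selectable)) {
        out <- c(out, paste0(pad, "    selectable: true"))
      }
    }
  }
  out
}

# Quote a scalar whenever plain YAML could reinterpret it.
yaml_scalar <- function(x, key = FALSE) {
  x <- as.character(x)
  if (!nzchar(x)) return('""')
  plain_ok <- grepl("^[A-Za-z_<][^#]*$", x) &&
    !grepl("(^[?&*!|>%@`'\"[:space:]-])|(:([[:space:]]|$))|[{}\\[\\],]", x,
           perl = TRUE) &&
    !grepl("^(true|false|yes|no|on|off|null|~)$", x, ignore.case = TRUE) &&
    x == trimws(x)
  if (plain_ok) return(x)
  paste0('"', gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", x)), '"')
}

#' List the variables a user (or language model) may select
#'
#' Connector nodes — intermediate variables whose only role is to link
#' property paths — are excluded, because the query builder resolves them
#' internally and they would only confuse the extraction stage.
#'
#' @param schema A `sparql_schema`.
#' @param explanations Optional named character vector or list mapping
#'   variable names to explanation sentences; overrides any explanation
#'   embedded in the schema document. Names must exist in the schema.
#' @return A data frame with columns `name`, `example`, `explanation`, one row
#'   per non-connector node in document order.
#' @export
list_selectable_variables <- function(schema, explanations = NULL) {
  stopifnot(inherits(schema, "sparql_schema"))
  if (!is.null(explanations)) {
    expl <- unlist(explanations)
    unknown <- setdiff(names(expl), names(schema$nodes))
    if (length(unknown)) {
      stop("explanation supplied for unknown variable(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  } else {
    expl <- character(0)
  }
  keep <- vapply(schema$nodes, function(n) n$kind != "connector", logical(1))
  nodes <- schema$nodes[keep]
  data.frame(
    name = vapply(nodes, `[[`, character(1), "name"),
    example = vapply(nodes, `[[`, character(1), "example"),
    explanation = vapply(nodes, function(n) {
      if (n$name %in% names(expl)) as.character(expl[[n$name]]) else n$explanation
    }, character(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Merge several schemas into one forest
#'
#' Supports cross-database querying: the merged schema keeps every input root,
#' so one request can draw variables from several databases. Variable names
#' must be disjoint and shared prefix labels must map to the same namespace.
#'
#' @param schemas A list of `sparql_schema` objects (at least one).
#' @param name Dataset label for the merged schema; defaults to the input
#'   names joined with `"+"`.
#' @return A `sparql_schema` whose roots are the concatenated input roots.
#' @export
merge_schemas <- function(schemas, name = NULL) {
  stopifnot(is.list(schemas), length(schemas) >= 1L)
  for (s in schemas) stopifnot(inherits(s, "sparql_schema"))
  all_names <- unlist(lapply(schemas, function(s) names(s$nodes)))
  dup <- unique(all_names[duplicated(all_names)])
  if (length(dup)) {
    stop("variable-name collision across schemas: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  prefixes <- character(0)
  for (s in schemas) {
    for (lbl in names(s$prefixes)) {
      if (lbl %in% names(prefixes) && prefixes[[lbl]] != s$prefixes[[lbl]]) {
        stop("prefix label '", lbl, "' maps to different namespaces: ",
             prefixes[[lbl]], " vs ", s$prefixes[[lbl]], call. = FALSE)
      }
      prefixes[lbl] <- s$prefixes[[lbl]]
    }
  }
  structure(
    list(
      name = name %||% paste(vapply(schemas, `[[`, character(1), "name"),
                             collapse = "+"),
      prefixes = prefixes,
      nodes = do.call(c, lapply(schemas, `[[`, "nodes")),
      edges = do.call(rbind, lapply(schemas, `[[`, "edges")),
      roots = unlist(lapply(schemas, `[[`, "roots"))
    ),
    class = "sparql_schema"
  )
}

#' Edge path from a variable's subject-root down to the variable
#'
#' @param schema A `sparql_schema`.
#' @param variable A variable name present in the schema.
#' @return A data frame of edges (`parent`, `predicate`, `child`) ordered from
#'   the root towards the variable; zero rows when the variable is a root.
#' @export
path_to_root <- function(schema, variable) {
  stopifnot(inherits(schema, "sparql_schema"))
  if (!variable %in% names(schema$nodes)) {
    stop("unknown variable '", variable, "'", call. = FALSE)
  }
  path <- list()
  cur <- variable
  while (!cur %in% schema$roots) {
    row <- schema$edges[schema$edges$child == cur, , drop = FALSE]
    stopifnot(nrow(row) == 1L)
    path[[length(path) + 1L]] <- row
    cur <- row$parent[[1]]
  }
  if (length(path) == 0L) {
    return(schema$edges[0L, , drop = FALSE])
  }
  do.call(rbind, rev(path))
}

#' @export
print.sparql_schema <- function(x, ...) {
  cat("<sparql_schema> ", x$name, "\n", sep = "")
  cat("  roots:  ", paste(x$roots, collapse = ", "), "\n", sep = "")
  cat("  nodes:  ", length(x$nodes), " (",
      sum(vapply(x$nodes, function(n) n$kind == "connector", logical(1))),
      " connector)\n", sep = "")
  cat("  edges:  ", nrow(x$edges), "\n", sep = "")
  cat("  prefixes: ", paste(names(x$prefixes), collapse = ", "), "\n", sep = "")
  invisible(x)
}
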