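# Synthetic fixtures: random schemas and schema-conforming Turtle graphs.
# These emulate the structural premise of curated RDF databases — every entry
# of a dataset instantiates the same tree-shaped subgraph pattern — so the
# whole pipeline (build, execute, score) can be exercised offline. They do
# not emulate the linguistic variety of real questions or the heterogeneity
# of real endpoints.

#' Generate a random schema
#'
#' Draws a forest of named variables: 1–`max_roots` subject-roots, each with a
#' random subtree of leaf objects and (optionally) connector nodes with their
#' own children, plus example values and short explanations. Intended for
#' property-style tests and fixture campaigns; the draw is a pure function of
#' the RNG state, so wrap calls in `set.seed()` for reproducibility.
#'
#' @param n_nodes Target number of non-root nodes per root (1–6 is typical).
#' @param max_roots Maximum number of subject-roots.
#' @param p_connector Probability that an internal slot becomes a connector
#'   node with children rather than a leaf.
#' @param tag Label distinguishing the variable namespace (lets several draws
#'   be merged without name collisions).
#' @return A `sparql_schema`.
#' @export
random_schema <- function(n_nodes = 4L, max_roots = 2L, p_connector = 0.3,
                          tag = "d1") {
  n_roots <- sample.int(max_roots, 1L)
  schemas <- lapply(seq_len(n_roots), function(r) {
    rt <- paste0("Root_", tag, "_", r)
    ns <- paste0("http://example.org/", tag, "/", r, "/")
    lines <- c(
      "prefixes:",
      paste0("  ex", r, ": <", ns, ">"),
      "model:",
      paste0("  - ", rt, " ex", r, ":entry1:"),
      paste0("      - a: ex", r, ":Entry")
    )
    n_kids <- max(1L, stats::rpois(1L, n_nodes - 1L) + 1L)
    kid_id <- 0L
    for (k in seq_len(n_kids)) {
      kid_id <- kid_id + 1L
      leaf <- paste0("var_", tag, "_", r, "_", kid_id)
      if (stats::runif(1) < p_connector) {
        conn <- paste0("conn_", tag, "_", r, "_", kid_id)
        kid_id <- kid_id + 1L
        inner <- paste0("var_", tag, "_", r, "_", kid_id)
        lines <- c(lines,
                   paste0("      - ex", r, ":p", k, ":"),
                   paste0("          - ", conn, ": \"\""),
                   paste0("          - ex", r, ":q", k, ":"),
                   paste0("              ", inner, ": sample_", inner),
                   paste0("              explanation: \"Value of ", inner,
                          " reached through an intermediate node.\""))
      } else {
        lines <- c(lines,
                   paste0("      - ex", r, ":p", k, ":"),
                   paste0("          ", leaf, ": sample_", leaf),
                   paste0("          explanation: \"The ", leaf,
                          " attribute of an entry.\""))
      }
    }
    parse_schema(paste(lines, collapse = "\n"))
  })
  out <- if (length(schemas) == 1L) schemas[[1]] else merge_schemas(schemas)
  out$name <- paste0("synthetic_", tag)
  out
}

#' Specification for a synthetic fixture graph
#'
#' @param schema A `sparql_schema`.
#' @param n_entries Number of database entries to mint per subject-root
#'   (≥ 1).
#' @param seed Integer seed; the graph is a deterministic function of the
#'   spec.
#' @param value_pools Optional named list mapping variable names to pools of
#'   lexical forms; object values for that variable are drawn reproducibly
#'   from the pool (typed by the same rule as query parameters). Without a
#'   pool, values are synthesized as `"<variable>_<k>"` literals with `k`
#'   drawn from a small range so that entries can share values.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(schema, n_entries, seed = 1L, value_pools = NULL) {
  stopifnot(inherits(schema, "sparql_schema"), n_entries >= 1L)
  if (!is.null(value_pools)) {
    stopifnot(is.list(value_pools), all(lengths(value_pools) >= 1L))
    unknown <- setdiff(names(value_pools), names(schema$nodes))
    if (length(unknown)) {
      stop("value pool for unknown variable(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(schema = schema, n_entries = as.integer(n_entries),
                 seed = as.integer(seed), value_pools = value_pools),
            class = "fixture_spec")
}

#' Generate a Turtle graph conforming to a schema
#'
#' For each of `n_entries` entries per subject-root the generator mints a
#' deterministic subject IRI, emits one `rdf:type` triple per declared root
#' type, and one triple per schema edge. Connector nodes become labelled
#' intermediate blank nodes unique to the entry; leaf values come from the
#' spec's value pools or are synthesized. Byte-identical output for identical
#' specs.
#'
#' @param spec A [fixture_spec()].
#' @return Turtle text (single string).
#' @export
generate_fixture_graph <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  schema <- spec$schema
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)

  triples <- list()
  add <- function(s, p, o) triples[[length(triples) + 1L]] <<- c(s, p, o)

  value_for <- function(variable, entry) {
    pool <- spec$value_pools[[variable]]
    if (!is.null(pool)) {
      v <- pool[[sample.int(length(pool), 1L)]]
      parameter_term(as.character(v), schema$prefixes)$canonical
    } else {
      k <- sample.int(max(2L, ceiling(spec$n_entries / 2)), 1L)
      term_literal(paste0(variable, "_", k))
    }
  }

  emit_subtree <- function(node, subject, entry) {
    kids <- schema$edges[schema$edges$parent == node, , drop = FALSE]
    for (i in seq_len(nrow(kids))) {
      child <- kids$child[[i]]
      pred <- resolve_term(kids$predicate[[i]], schema$prefixes)
      if (schema$nodes[[child]]$kind == "connector") {
        bn <- term_blank(paste0(child, "_e", entry))
        add(subject, pred, bn)
        emit_subtree(child, bn, entry)
      } else {
        add(subject, pred, value_for(child, entry))
        # a flagged-selectable internal node still has children to emit
        if (child %in% schema$edges$parent) {
          bn <- term_blank(paste0(child, "_e", entry))
          add(subject, pred, bn)
          emit_subtree(child, bn, entry)
        }
      }
    }
  }

  for (root in schema$roots) {
    ns <- paste0("http://example.org/fixture/", root, "/")
    types <- vapply(schema$nodes[[root]]$rdf_types, resolve_term,
                    character(1), prefixes = schema$prefixes,
                    USE.NAMES = FALSE)
    for (e in seq_len(spec$n_entries)) {
      subj <- term_iri(paste0(ns, "entry", e))
      for (tp in types) add(subj, RDF_TYPE, tp)
      emit_subtree(root, subj, e)
    }
  }

  tri <- as.data.frame(do.call(rbind, triples), stringsAsFactors = FALSE)
  names(tri) <- c("s", "p", "o")
  render_turtle(list(triples = tri, prefixes = schema$prefixes))
}

#' Answer a request by direct graph traversal (no SPARQL)
#'
#' Independent oracle for the query pipeline: starting from the subjects
#' typed as each relevant root, it walks the schema paths edge by edge,
#' enumerates all bindings, takes the cross product across roots, applies
#' parameter bindings as exact term filters, and projects the requested
#' variables. No query text is built or parsed anywhere on this path.
#'
#' @param schema A `sparql_schema`.
#' @param request A [query_request()] valid against `schema`.
#' @param graph Turtle text or an `rdf_graph`.
#' @return A [result_table()] (distinct rows, same normalisation as
#'   [execute_local()]).
#' @export
oracle_answer <- function(schema, request, graph) {
  stopifnot(inherits(schema, "sparql_schema"),
            inherits(request, "query_request"))
  g <- if (inherits(graph, "rdf_graph")) graph else parse_turtle(graph)
  tri <- g$triples

  needed <- unique(c(request$variables, request$parameters$variable))
  unknown <- setdiff(needed, names(schema$nodes))
  if (length(unknown)) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  roots_hit <- schema$roots[schema$roots %in%
                              unique(vapply(needed, function(v)
                                schema$nodes[[v]]$root, character(1)))]

  # bindings for one root: start from typed subjects, extend edge by edge
  bind_root <- function(root) {
    vars_here <- needed[vapply(needed, function(v)
      schema$nodes[[v]]$root == root, logical(1))]
    edge_rows <- list()
    for (v in vars_here) {
      p <- path_to_root(schema, v)
      for (i in seq_len(nrow(p))) {
        key <- paste(p$parent[[i]], p$predicate[[i]], p$child[[i]], sep = "\r")
        edge_rows[[key]] <- p[i, , drop = FALSE]
      }
    }
    types <- vapply(schema$nodes[[root]]$rdf_types, resolve_term,
                    character(1), prefixes = schema$prefixes,
                    USE.NAMES = FALSE)
    subjects <- tri$s[tri$p == RDF_TYPE & tri$o %in% types[[1]]]
    for (tp in types[-1]) {
      subjects <- intersect(subjects, tri$s[tri$p == RDF_TYPE & tri$o == tp])
    }
    sols <- lapply(unique(subjects), function(s)
      stats::setNames(s, root))
    # walk edges in path order (parents always precede children)
    ordered <- edge_rows[order(vapply(names(edge_rows), function(k) {
      e <- edge_rows[[k]]
      nrow(path_to_root(schema, e$child[[1]]))
    }, numeric(1)))]
    for (e in ordered) {
      pred <- resolve_term(e$predicate[[1]], schema$prefixes)
      parent <- e$parent[[1]]
      child <- e$child[[1]]
      nxt <- list()
      for (sol in sols) {
        objs <- tri$o[tri$p == pred & tri$s == sol[[parent]]]
        for (o in objs) {
          ext <- sol
          ext[child] <- o
          nxt[[length(nxt) + 1L]] <- ext
        }
      }
      sols <- nxt
    }
    sols
  }

  sols <- list(stats::setNames(character(0), character(0)))
  for (root in roots_hit) {
    part <- bind_root(root)
    sols <- unlist(lapply(sols, function(a)
      lapply(part, function(b) c(a, b))), recursive = FALSE)
    if (length(sols) == 0L) break
  }

  # exact term filters; multiple values for one variable are a disjunction
  for (v in unique(request$parameters$variable)) {
    vals <- request$parameters$value[request$parameters$variable == v]
    tgts <- vapply(vals, function(val)
      parameter_term(val, schema$prefixes)$canonical, character(1),
      USE.NAMES = FALSE)
    sols <- Filter(function(sol) v %in% names(sol) && sol[[v]] %in% tgts,
                   sols)
  }

  solutions_to_table(sols, request$variables,
                     star = length(request$variables) == 0L, distinct = TRUE)
}
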