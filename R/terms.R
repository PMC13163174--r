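# RDF term handling shared by the schema, builder, Turtle and execution code.
#
# Terms are carried around as canonical strings:
#   IRI      -> "<http://...>"
#   blank    -> "_:label"
#   literal  -> "\"lexical\""  (optionally + "^^<dt>" or "@lang")
# Canonical strings double as join keys in the triple store, so two terms are
# identical iff their strings are identical.

RDF_TYPE <- "<http://www.w3.org/1999/02/22-rdf-syntax-ns#type>"

.pname_re <- "^([A-Za-z][A-Za-z0-9_.-]*):([^[:space:]]+)$"
.identifier_re <- "^[\\p{L}_][\\p{L}\\p{N}_]*$"

is_identifier <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) &&
    grepl(.identifier_re, x, perl = TRUE)
}

is_absolute_iri <- function(x) {
  grepl("^[A-Za-z][A-Za-z0-9+.-]*:", x) && !grepl("[[:space:]<>\"{}|\\\\^`]", x)
}

is_prefixed_name <- function(x) grepl(.pname_re, x)

term_iri <- function(iri) paste0("<", iri, ">")

term_blank <- function(label) paste0("_:", label)

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x
}

unescape_literal <- function(x) {
  out <- character(length(x))
  for (k in seq_along(x)) {
    chars <- strsplit(x[[k]], "", fixed = TRUE)[[1]]
    buf <- character(0)
    i <- 1L
    while (i <= length(chars)) {
      ch <- chars[[i]]
      if (ch == "\\" && i < length(chars)) {
        nxt <- chars[[i + 1L]]
        buf <- c(buf, switch(nxt, n = "\n", r = "\r", t = "\t", nxt))
        i <- i + 2L
      } else {
        buf <- c(buf, ch)
        i <- i + 1L
      }
    }
    out[[k]] <- paste0(buf, collapse = "")
  }
  out
}

term_literal <- function(lex, datatype = NULL, lang = NULL) {
  base <- paste0("\"", escape_literal(lex), "\"")
  if (!is.null(lang)) return(paste0(base, "@", lang))
  if (!is.null(datatype)) return(paste0(base, "^^", datatype))
  base
}

term_kind <- function(term) {
  if (startsWith(term, "<")) "iri"
  else if (startsWith(term, "_:")) "blank"
  else if (startsWith(term, "\"")) "literal"
  else stop("not a canonical term: ", term)
}

#' @keywords internal
#' @noRd
validate_prefix_map <- function(prefixes) {
  if (length(prefixes) == 0L) return(invisible(prefixes))
  labels <- names(prefixes)
  if (is.null(labels) || any(labels == "")) {
    stop("prefix map entries must be named", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("duplicate prefix label: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  if ("a" %in% labels) {
    stop("prefix label 'a' is reserved (rdf:type shorthand)", call. = FALSE)
  }
  bad <- labels[!vapply(unname(prefixes), is_absolute_iri, logical(1))]
  if (length(bad)) {
    stop("prefix namespace is not an absolute IRI: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(prefixes)
}

# Resolve a predicate/type written as a prefixed name or absolute IRI to the
# canonical <iri> form. "a" resolves to rdf:type.
resolve_term <- function(x, prefixes) {
  if (identical(x, "a")) return(RDF_TYPE)
  if (startsWith(x, "<") && endsWith(x, ">")) return(x)
  m <- regmatches(x, regexec(.pname_re, x))[[1]]
  if (length(m) == 3L) {
    label <- m[[2]]
    if (!label %in% names(prefixes)) {
      stop("undeclared prefix '", label, "' in '", x, "'", call. = FALSE)
    }
    return(term_iri(paste0(prefixes[[label]], m[[3]])))
  }
  if (is_absolute_iri(x)) return(term_iri(x))
  stop("cannot resolve '", x, "' as a prefixed name or IRI", call. = FALSE)
}

# Prefix label used by a schema-level name ("up:Protein" -> "up"), or NA.
prefix_label_of <- function(x) {
  if (identical(x, "a")) return(NA_character_)
  if (startsWith(x, "<")) return(NA_character_)
  m <- regmatches(x, regexec(.pname_re, x))[[1]]
  if (length(m) == 3L) m[[2]] else NA_character_
}

# Parameter-value typing rule: a declared prefixed name is emitted as such,
# an explicitly double-quoted value is taken verbatim as a literal, anything
# else becomes a plain literal.
parameter_term <- function(value, prefixes) {
  stopifnot(is.character(value), length(value) == 1L)
  if (grepl("^\".*\"$", value)) {
    return(list(render = value, canonical = value))
  }
  m <- regmatches(value, regexec(.pname_re, value))[[1]]
  if (length(m) == 3L) {
    label <- m[[2]]
    if (!label %in% names(prefixes)) {
      stop("parameter value '", value,
           "' looks like a prefixed name but prefix '", label,
           "' is not declared in the schema", call. = FALSE)
    }
    return(list(render = value,
                canonical = term_iri(paste0(prefixes[[label]], m[[3]]))))
  }
  lit <- term_literal(value)
  list(render = lit, canonical = lit)
}

# Normalisation policy for result cells: IRIs compare as full IRI strings,
# literals by bare lexical form (datatype / language tag stripped), blank
# nodes by a stable per-table label assigned in first-seen order.
normalize_cells <- function(terms) {
  blank_map <- new.env(parent = emptyenv())
  n_blank <- 0L
  vapply(terms, function(term) {
    kind <- term_kind(term)
    if (kind == "iri") {
      substr(term, 2L, nchar(term) - 1L)
    } else if (kind == "blank") {
      key <- term
      if (is.null(blank_map[[key]])) {
        n_blank <<- n_blank + 1L
        assign(key, paste0("_:b", n_blank), envir = blank_map)
      }
      blank_map[[key]]
    } else {
      m <- regmatches(term, regexec('^"(.*)"(\\^\\^.*|@[A-Za-z-]+)?$', term))[[1]]
      unescape_literal(m[[2]])
    }
  }, character(1), USE.NAMES = FALSE)
}
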