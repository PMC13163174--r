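# Restricted Turtle reader and writer.
#
# Covers the constructs the fixture generator and the query pipeline use:
# @prefix / PREFIX directives, IRIs in angle brackets, prefixed names, the
# 'a' keyword, blank-node labels (_:x), plain / typed / language-tagged
# string literals, integers, and predicate (';') and object (',') lists.
# Quoted structures, collections, anonymous blank nodes and multi-line
# literals are out of scope and rejected with a parse error.

#' Parse a (restricted) Turtle document into a triple table
#'
#' @param ttl Turtle text as a single string or character vector of lines.
#' @return An object of class `rdf_graph`: list with `triples` (data frame
#'   `s`, `p`, `o` of canonical term strings) and `prefixes` (named
#'   character).
#' @export
parse_turtle <- function(ttl) {
  if (length(ttl) > 1L) ttl <- paste(ttl, collapse = "\n")
  toks <- tokenize_turtle(ttl)
  prefixes <- character(0)
  triples <- list()
  i <- 1L
  n <- length(toks)

  take <- function() {
    if (i > n) stop("unexpected end of Turtle document", call. = FALSE)
    tk <- toks[[i]]
    i <<- i + 1L
    tk
  }
  peek <- function() if (i <= n) toks[[i]] else NA_character_

  resolve_tok <- function(tk) {
    if (startsWith(tk, "<") || startsWith(tk, "_:") || startsWith(tk, "\"")) {
      return(tk)
    }
    if (tk == "a") return(RDF_TYPE)
    resolve_term(tk, prefixes)
  }

  while (i <= n) {
    tk <- take()
    if (tk %in% c("@prefix", "PREFIX")) {
      lbl <- take()
      if (!grepl("^[A-Za-z][A-Za-z0-9_.-]*:$", lbl)) {
        stop("malformed prefix label '", lbl, "' in Turtle", call. = FALSE)
      }
      iri <- take()
      if (!startsWith(iri, "<")) {
        stop("prefix namespace must be an <IRI>", call. = FALSE)
      }
      prefixes[sub(":$", "", lbl)] <- substr(iri, 2L, nchar(iri) - 1L)
      if (tk == "@prefix") {
        if (!identical(take(), ".")) {
          stop("expected '.' after @prefix directive", call. = FALSE)
        }
      } else if (identical(peek(), ".")) {
        i <- i + 1L
      }
      next
    }
    subj <- resolve_tok(tk)
    repeat {
      pred <- resolve_tok(take())
      repeat {
        obj <- resolve_tok(take())
        triples[[length(triples) + 1L]] <- c(subj, pred, obj)
        sep <- take()
        if (sep == ",") next
        if (sep == ";") break
        if (sep == ".") break
        stop("unexpected token '", sep, "' in Turtle statement", call. = FALSE)
      }
      if (sep == ".") break
      # after ';' either another predicate or a terminating '.'
      if (identical(peek(), ".")) {
        i <- i + 1L
        break
      }
    }
  }

  tri <- if (length(triples)) {
    as.data.frame(do.call(rbind, triples), stringsAsFactors = FALSE)
  } else {
    data.frame(s = character(0), p = character(0), o = character(0),
               stringsAsFactors = FALSE)
  }
  names(tri) <- c("s", "p", "o")
  structure(list(triples = tri, prefixes = prefixes), class = "rdf_graph")
}

tokenize_turtle <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
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
      if (j > n) stop("unterminated IRI in Turtle", call. = FALSE)
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
        } else if (cj == "\n") {
          stop("unterminated literal in Turtle", call. = FALSE)
        } else {
          buf <- paste0(buf, cj)
          j <- j + 1L
        }
      }
      if (!endsWith(buf, "\"") || nchar(buf) < 2L) {
        stop("unterminated literal in Turtle", call. = FALSE)
      }
      # optional datatype/lang suffix
      if (j + 1L <= n && chars[[j]] == "^" && chars[[j + 1L]] == "^") {
        j <- j + 2L
        if (j <= n && chars[[j]] == "<") {
          k <- j
          while (k <= n && chars[[k]] != ">") k <- k + 1L
          buf <- paste0(buf, "^^", paste0(chars[j:k], collapse = ""))
          j <- k + 1L
        } else {
          k <- j
          while (k <= n && grepl("[A-Za-z0-9_.:-]", chars[[k]])) k <- k + 1L
          buf <- paste0(buf, "^^", paste0(chars[j:(k - 1L)], collapse = ""))
          j <- k
        }
      } else if (j <= n && chars[[j]] == "@") {
        k <- j + 1L
        while (k <= n && grepl("[A-Za-z-]", chars[[k]])) k <- k + 1L
        buf <- paste0(buf, paste0(chars[j:(k - 1L)], collapse = ""))
        j <- k
      }
      toks <- c(toks, buf)
      i <- j
    } else if (ch %in% c(".", ";", ",")) {
      # '.' inside a prefixed name is handled in the word branch below;
      # a bare '.' here is a statement terminator
      toks <- c(toks, ch)
      i <- i + 1L
    } else {
      j <- i
      while (j <= n && !chars[[j]] %in% c(" ", "\t", "\n", "\r", ";", ",",
                                          "\"", "<", "#")) {
        j <- j + 1L
      }
      word <- paste0(chars[i:(j - 1L)], collapse = "")
      # a trailing '.' terminates the statement unless escaped into the name
      if (grepl("\\.$", word) && word != ".") {
        word <- sub("\\.$", "", word)
        toks <- c(toks, tokenize_word(word), ".")
      } else {
        toks <- c(toks, tokenize_word(word))
      }
      i <- j
    }
  }
  toks
}

tokenize_word <- function(word) {
  if (grepl("^-?[0-9]+$", word)) {
    return(term_literal(word,
                        datatype = "<http://www.w3.org/2001/XMLSchema#integer>"))
  }
  word
}

#' Serialize a triple table to Turtle
#'
#' One statement per triple, in table order, with prefix directives first and
#' IRIs compacted to prefixed names where a declared namespace matches.
#' Deterministic: the same graph serializes to byte-identical text.
#'
#' @param graph An `rdf_graph` (or a list with `triples` and `prefixes`).
#' @return Turtle text as a single string.
#' @export
render_turtle <- function(graph) {
  tri <- graph$triples
  prefixes <- graph$prefixes
  compact <- function(term) {
    if (startsWith(term, "<")) {
      iri <- substr(term, 2L, nchar(term) - 1L)
      if (identical(term, RDF_TYPE)) return("a")
      for (lbl in names(prefixes)) {
        ns <- prefixes[[lbl]]
        if (startsWith(iri, ns)) {
          local <- substring(iri, nchar(ns) + 1L)
          if (grepl("^[A-Za-z0-9_-]+$", local)) {
            return(paste0(lbl, ":", local))
          }
        }
      }
    }
    term
  }
  lines <- vapply(names(prefixes), function(lbl) {
    paste0("@prefix ", lbl, ": <", prefixes[[lbl]], "> .")
  }, character(1), USE.NAMES = FALSE)
  if (length(lines)) lines <- c(lines, "")
  for (k in seq_len(nrow(tri))) {
    lines <- c(lines, paste(compact(tri$s[[k]]), compact(tri$p[[k]]),
                            compact(tri$o[[k]]), "."))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @export
print.rdf_graph <- function(x, ...) {
  cat("<rdf_graph> ", nrow(x$triples), " triples, ",
      length(x$prefixes), " prefixes\n", sep = "")
  invisible(x)
}
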