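#' Jaccard coefficient between two rows (value sets)
#'
#' Row similarity for the execution-based metric: `|a ∩ b| / |a ∪ b|`.
#' Two empty sets score 1.0 (they agree perfectly on nothing).
#'
#' @param a,b Character vectors treated as sets (duplicates ignored).
#' @return A number in `[0, 1]`; symmetric in its arguments.
#' @export
row_jaccard <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (length(a) == 0L && length(b) == 0L) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Pairwise row-similarity matrix between two result tables
#'
#' @param G,Q [result_table()] objects (conventionally ground truth and
#'   generated).
#' @return An `N_g x N_q` numeric matrix `S` with `S[i, j]` the Jaccard
#'   coefficient between row `i` of `G` and row `j` of `Q`.
#' @export
similarity_matrix <- function(G, Q) {
  stopifnot(inherits(G, "result_table"), inherits(Q, "result_table"))
  ng <- length(G$rows)
  nq <- length(Q$rows)
  S <- matrix(0, nrow = ng, ncol = nq)
  for (i in seq_len(ng)) {
    for (j in seq_len(nq)) {
      S[i, j] <- row_jaccard(G$rows[[i]], Q$rows[[j]])
    }
  }
  S
}

#' Maximum-weight one-to-one matching of table rows
#'
#' Solves the assignment problem on a similarity matrix: each ground-truth
#' row is paired with at most one generated row so that the summed similarity
#' is maximal. The rectangular matrix is padded to square with zero weights
#' and solved with `clue::solve_LSAP`; pairs of zero weight are dropped from
#' the report (they cannot change the total). The total weight is unique even
#' when several matchings attain it; the reported pair set is deterministic.
#'
#' @param S Numeric matrix with entries in `[0, 1]` (any non-negative weights
#'   are accepted).
#' @return A list with `pairs` (two-column integer matrix of (i, j) indices,
#'   ordered by i) and `weight` (the maximal total similarity).
#' @export
optimal_matching <- function(S) {
  stopifnot(is.matrix(S), all(!is.na(S)), all(S >= 0))
  ng <- nrow(S)
  nq <- ncol(S)
  empty <- list(pairs = matrix(integer(0), ncol = 2L,
                               dimnames = list(NULL, c("g", "q"))),
                weight = 0)
  if (ng == 0L || nq == 0L) return(empty)
  n <- max(ng, nq)
  P <- matrix(0, n, n)
  P[seq_len(ng), seq_len(nq)] <- S
  sol <- clue::solve_LSAP(P, maximum = TRUE)
  g <- seq_len(n)
  q <- as.integer(sol)
  keep <- g <= ng & q <= nq
  g <- g[keep]
  q <- q[keep]
  w <- S[cbind(g, q)]
  nz <- w > 0
  list(pairs = cbind(g = g[nz], q = q[nz]), weight = sum(w))
}

#' Execution-based similarity of two result tables
#'
#' The headline score: rows are optimally matched one-to-one by Jaccard
#' similarity and the summed similarity is normalised by `max(N_g, N_q)`, so
#' every unmatched row in the larger table counts as zero. Conventions for
#' the cases the formula leaves open: two empty tables score 1.0, one empty
#' table against a non-empty one scores 0.0.
#'
#' The metric is purely lexical: semantically equivalent but differently
#' written values (e.g. `Mouse` vs `Mus musculus`) contribute nothing, which
#' is a known property of execution-based scoring, addressable upstream by
#' entity normalisation, not here.
#'
#' @param G,Q [result_table()] objects.
#' @return A number in `[0, 1]`; symmetric and invariant under row
#'   permutation of either table.
#' @export
table_similarity <- function(G, Q) {
  stopifnot(inherits(G, "result_table"), inherits(Q, "result_table"))
  ng <- length(G$rows)
  nq <- length(Q$rows)
  if (ng == 0L && nq == 0L) return(1)
  if (ng == 0L || nq == 0L) return(0)
  m <- optimal_matching(similarity_matrix(G, Q))
  m$weight / max(ng, nq)
}

#' Jaccard coefficient between predicted and ground-truth item sets
#'
#' Used to score variable selection (sets of names) and parameter extraction
#' (sets of exact (variable, value) pairs: a pair differing only in its value
#' counts as a different item).
#'
#' @param predicted,truth Character vectors, or lists of length-2 vectors /
#'   two-column data frames for parameter pairs.
#' @return `|∩| / |∪|`; 1.0 when both sets are empty.
#' @export
set_jaccard <- function(predicted, truth) {
  key <- function(x) {
    if (is.data.frame(x)) {
      stopifnot(ncol(x) >= 2L)
      return(unique(paste(x[[1]], x[[2]], sep = "\r")))
    }
    if (is.list(x)) {
      return(unique(vapply(x, function(p) paste(p, collapse = "\r"),
                           character(1))))
    }
    unique(as.character(x))
  }
  a <- key(predicted)
  b <- key(truth)
  if (length(a) == 0L && length(b) == 0L) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Five-bin distribution of scores
#'
#' Bins scores in `[0, 1]` into the five ranges used to summarise extraction
#' accuracy: `x = 0`, `0 < x < 0.5`, `x = 0.5`, `0.5 < x < 1`, `x = 1`.
#' Boundary classification is exact.
#'
#' @param scores Numeric vector with all values in `[0, 1]`.
#' @return A named integer vector of length 5; the counts sum to
#'   `length(scores)`.
#' @export
score_distribution <- function(scores) {
  scores <- as.numeric(scores)
  if (any(is.na(scores)) || any(scores < 0) || any(scores > 1)) {
    stop("scores must all lie in [0, 1]", call. = FALSE)
  }
  c(`x=0` = sum(scores == 0),
    `0<x<0.5` = sum(scores > 0 & scores < 0.5),
    `x=0.5` = sum(scores == 0.5),
    `0.5<x<1` = sum(scores > 0.5 & scores < 1),
    `x=1` = sum(scores == 1))
}
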