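# Benchmark campaigns: run the extract -> build -> execute loop over a set of
# question records and score each against its expert ground truth, the way
# text-to-SPARQL systems are compared across whole question sets.

#' Read / write benchmark files
#'
#' A benchmark is a YAML (or JSON) document with a top-level `records` list.
#' Each record has keys `id`, `question`, `truth_variables` (list of names),
#' `truth_parameters` (list of `[variable, value]` pairs) and optionally
#' `paraphrase_of` (the id of the original question it rephrases). Ground
#' truth is stored as variables + parameters — the form experts curate — and
#' queries are derived from them, never hand-written.
#'
#' @param path Benchmark file path (`.yaml`/`.yml` or `.json`).
#' @return A list of benchmark records (each a named list).
#' @export
read_benchmark <- function(path) {
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  validate_benchmark(doc$records %||% doc)
}

validate_benchmark <- function(records) {
  stopifnot(is.list(records), length(records) >= 1L)
  ids <- vapply(records, function(r) as.character(r$id %||% ""), character(1))
  if (any(!nzchar(ids)) || anyDuplicated(ids)) {
    stop("every benchmark record needs a unique non-empty id", call. = FALSE)
  }
  lapply(records, function(r) {
    if (is.null(r$question) || !nzchar(r$question)) {
      stop("benchmark record '", r$id, "' has no question", call. = FALSE)
    }
    if (!is.null(r$paraphrase_of) && !r$paraphrase_of %in% ids) {
      stop("record '", r$id, "' paraphrases unknown record '",
           r$paraphrase_of, "'", call. = FALSE)
    }
    list(
      id = as.character(r$id),
      question = as.character(r$question),
      truth_variables = as.character(unlist(r$truth_variables %||% list())),
      truth_parameters = lapply(r$truth_parameters %||% list(), function(p) {
        stopifnot(length(p) == 2L)
        c(as.character(p[[1]]), as.character(p[[2]]))
      }),
      paraphrase_of = if (!is.null(r$paraphrase_of))
        as.character(r$paraphrase_of)
    )
  })
}

#' @rdname read_benchmark
#' @param records A list of benchmark records.
#' @export
write_benchmark <- function(records, path) {
  writeLines(yaml::as.yaml(list(records = records)), con = path,
             useBytes = TRUE)
  invisible(path)
}

truth_request <- function(record) {
  query_request(record$truth_variables, record$truth_parameters)
}

#' Run a scored benchmark campaign
#'
#' For every record: run the extraction pipeline, build the query, execute it,
#' and score it against the ground truth on three axes — execution-based
#' table similarity, variable-set Jaccard, and parameter-set Jaccard (exact
#' (variable, value) pairs) — plus the count of strict-copy warnings. A
#' record whose extraction, build or execution fails scores 0 for table
#' similarity, is flagged, and never aborts the campaign; this is distinct
#' from two legitimately empty result tables, which score 1.
#'
#' @param records Benchmark records (see [read_benchmark()]).
#' @param schema A `sparql_schema`.
#' @param client An [llm_client()].
#' @param graph Turtle text, file path or `rdf_graph` for local execution, or
#'   an [endpoint_config()] for remote execution.
#' @param mode Variables-info presentation mode (`"VwE"`, `"VwoE"`,
#'   `"VinS"`).
#' @param explanations Optional explanations passed to the extraction stage.
#' @param seed Integer recorded in the report and set before the run, so
#'   campaigns with deterministic clients are bit-reproducible.
#' @return An object of class `campaign_report`: `per_record` data frame
#'   (`id`, `table_similarity`, `variable_jaccard`, `parameter_jaccard`,
#'   `strict_copy_warnings`, `failed`, `error`), `means`, `bins` (five-bin
#'   distributions for all three scores), and `meta`.
#' @export
run_campaign <- function(records, schema, client, graph,
                         mode = c("VwE", "VwoE", "VinS"),
                         explanations = NULL, seed = 1L) {
  mode <- match.arg(mode)
  records <- validate_benchmark(records)
  set.seed(seed)
  execute <- function(query_text, origin) {
    if (inherits(graph, "endpoint_config")) {
      execute_remote(query_text, graph, origin = origin)
    } else {
      execute_local(query_text, graph, origin = origin)
    }
  }

  rows <- lapply(records, function(rec) {
    truth_req <- truth_request(rec)
    truth_tab <- execute(build_query(schema, truth_req)$text, origin = "G")
    out <- list(id = rec$id, table_similarity = 0,
                variable_jaccard = 0, parameter_jaccard = 0,
                strict_copy_warnings = 0L, failed = TRUE, error = "")
    res <- tryCatch({
      ext <- extract_request(rec$question, schema, client,
                             explanations = explanations, mode = mode)
      qry <- build_query(schema, as_query_request(ext))
      tab <- execute(qry$text, origin = "Q")
      list(ext = ext, tab = tab)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$error <- conditionMessage(res)
    } else {
      out$table_similarity <- table_similarity(truth_tab, res$tab)
      out$variable_jaccard <- set_jaccard(res$ext$variables,
                                          rec$truth_variables)
      out$parameter_jaccard <- set_jaccard(
        res$ext$parameters,
        lapply(rec$truth_parameters, identity))
      out$strict_copy_warnings <- length(res$ext$warnings)
      out$failed <- FALSE
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  per_record <- do.call(rbind, rows)

  means <- c(table_similarity = mean(per_record$table_similarity),
             variable_jaccard = mean(per_record$variable_jaccard),
             parameter_jaccard = mean(per_record$parameter_jaccard))
  bins <- list(
    table_similarity = score_distribution(per_record$table_similarity),
    variable_jaccard = score_distribution(per_record$variable_jaccard),
    parameter_jaccard = score_distribution(per_record$parameter_jaccard)
  )
  structure(
    list(per_record = per_record, means = means, bins = bins,
         meta = list(seed = seed, mode = mode, client = client$model_id,
                     n_records = length(records))),
    class = "campaign_report"
  )
}

#' @export
print.campaign_report <- function(x, ...) {
  cat("<campaign_report> ", x$meta$n_records, " records, mode ", x$meta$mode,
      ", client ", x$meta$client, ", seed ", x$meta$seed, "\n\n", sep = "")
  cat(format_report_text(x))
  invisible(x)
}

#' Plain-text rendering of a campaign report
#'
#' A means table plus the five-bin distribution of each score; deterministic,
#' suitable for byte-comparison of reruns.
#'
#' @param report A `campaign_report`.
#' @return A single string.
#' @export
format_report_text <- function(report) {
  stopifnot(inherits(report, "campaign_report"))
  lines <- c("score                 mean")
  for (nm in names(report$means)) {
    lines <- c(lines, sprintf("%-20s %6.3f", nm, report$means[[nm]]))
  }
  lines <- c(lines, "", paste("bins:", paste(names(report$bins$table_similarity),
                                             collapse = "  ")))
  for (nm in names(report$bins)) {
    lines <- c(lines, sprintf("%-20s %s", nm,
                              paste(sprintf("%5d", report$bins[[nm]]),
                                    collapse = "  ")))
  }
  flagged <- report$per_record$id[report$per_record$failed]
  if (length(flagged)) {
    lines <- c(lines, "", paste("failed records:",
                                paste(flagged, collapse = ", ")))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Export a campaign report as a structured record
#'
#' @param report A `campaign_report`.
#' @param path Optional path: when given, the record is written there as JSON
#'   (deterministic key order) and the path returned invisibly.
#' @return The report as a plain list (or the path, invisibly).
#' @export
report_record <- function(report, path = NULL) {
  stopifnot(inherits(report, "campaign_report"))
  rec <- list(
    meta = report$meta,
    means = as.list(report$means),
    bins = lapply(report$bins, as.list),
    per_record = report$per_record
  )
  if (!is.null(path)) {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(path))
  }
  rec
}
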