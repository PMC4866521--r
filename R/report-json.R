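REPORT_SCHEMA_VERSION <- "1.0"

.payloadToList <- function(p) {
  if (is.null(p)) return(NULL)
  list(kind = p@kind, series = p@series, annotations = p@annotations)
}

.verdictToList <- function(v) {
  list(name = v@name,
       status = v@status,
       statistic = if (is.na(v@statistic)) NULL else v@statistic,
       threshold = if (all(is.na(v@threshold))) NULL else I(v@threshold),
       p_value = if (is.na(v@pValue)) NULL else v@pValue,
       message = v@message,
       plot = .payloadToList(v@plot))
}

.reportToList <- function(r) {
  list(query_id = r@queryId,
       n_hits = r@nHits,
       score = if (is.na(r@score)) NULL else r@score,
       verdicts = lapply(r@verdicts, .verdictToList))
}

#' Write the JSON report
#'
#' One top-level document: schema version, run metadata (tool version,
#' configuration snapshot, input file names, timestamp), then an array of
#' per-query objects carrying every verdict's status, statistic,
#' threshold, p-value, message and plot payload.  Key order is stable so
#' identical runs produce identical bytes.
#'
#' @param reports list of [QueryReport-class].
#' @param path output file.
#' @param config the [gvConfig()] used for the run.
#' @param inputs named list of input file names (free-form metadata).
#' @param timestamp run timestamp string; pass a fixed value for
#'   byte-reproducible output.
#' @return the path, invisibly.
#' @export
renderJson <- function(reports, path, config = gvConfig(),
                       inputs = list(),
                       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")) {
  doc <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    metadata = list(
      tool = "genecheck",
      version = as.character(utils::packageVersion("genecheck")),
      timestamp = timestamp,
      inputs = inputs,
      config = unclass(config)),
    queries = lapply(reports, .reportToList))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

.listToPayload <- function(x) {
  if (is.null(x)) return(NULL)
  new("PlotPayload", kind = x$kind,
      series = lapply(x$series, as.numeric),
      annotations = x$annotations)
}

.listToVerdict <- function(x) {
  .newVerdict(x$name, x$status,
              statistic = if (is.null(x$statistic)) NA_real_ else x$statistic,
              threshold = if (is.null(x$threshold)) NA_real_
                          else as.numeric(unlist(x$threshold)),
              pValue = if (is.null(x$p_value)) NA_real_ else x$p_value,
              message = x$message,
              plot = .listToPayload(x$plot))
}

#' Read a JSON report back into QueryReport objects
#'
#' Inverse of [renderJson()]; useful for downstream tooling and for
#' verifying that serialisation is lossless.
#'
#' @param path JSON report file.
#' @return list with `metadata` (list) and `reports` (list of
#'   [QueryReport-class]).
#' @export
readReportJson <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  reports <- lapply(doc$queries, function(q) {
    new("QueryReport", queryId = q$query_id, nHits = as.integer(q$n_hits),
        verdicts = lapply(q$verdicts, .listToVerdict),
        score = if (is.null(q$score)) NA_integer_ else as.integer(q$score))
  })
  list(metadata = doc$metadata, reports = reports)
}
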