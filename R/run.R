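#' Run a full validation end-to-end
#'
#' Reads the query FASTA and the pre-computed BLAST output, executes every
#' applicable validation for each query in input order, and writes the
#' requested report formats into `outputDir`.  Queries without BLAST rows
#' are processed with the BLAST-dependent analyses skipped; BLAST query
#' ids absent from the FASTA raise a warning.  A failure inside one
#' analysis is recorded as an `error` verdict without aborting the run.
#'
#' @param inputFasta FASTA file of gene predictions (protein or
#'   nucleotide).
#' @param blastOutput pre-computed BLAST output for those queries (blastp
#'   for protein, blastx for nucleotide queries).
#' @param blastFormat "tabular" (outfmt 6/7) or "xml".
#' @param columns column declaration for tabular input (see
#'   [parseBlastTabular()]).
#' @param outputDir directory for the report files (created if needed).
#' @param formats subset of c("json", "tsv", "html").
#' @param topHits hits entering each analysis, most significant first.
#' @param hitFasta optional FASTA of full-length hit sequences for the
#'   conserved-regions profile.
#' @param config a [gvConfig()] list of thresholds.
#' @param alphabet NULL to auto-detect, or "protein"/"nucleotide" to
#'   force.
#' @param timestamp run timestamp written into the reports; pass a fixed
#'   string for byte-reproducible output.
#' @param quiet suppress the run log.
#' @return invisibly, a list with `reports` (list of
#'   [QueryReport-class]) and `files` (paths written).
#' @export
runValidation <- function(inputFasta, blastOutput,
                          blastFormat = c("tabular", "xml"),
                          columns = DEFAULT_TABULAR_COLUMNS,
                          outputDir = ".",
                          formats = c("json", "tsv", "html"),
                          topHits = 10L, hitFasta = NULL,
                          config = gvConfig(), alphabet = NULL,
                          timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                          quiet = FALSE) {
  blastFormat <- match.arg(blastFormat)
  formats <- match.arg(formats, several.ok = TRUE)
  config$topHits <- as.integer(topHits)
  queries <- readQueries(inputFasta, alphabet)
  hitsMap <- if (blastFormat == "tabular")
    parseBlastTabular(blastOutput, columns, maxHits = config$maxHits)
  else parseBlastXml(blastOutput, maxHits = config$maxHits)
  qids <- vapply(queries, function(q) q@id, character(1))
  orphans <- setdiff(names(hitsMap), qids)
  if (length(orphans))
    warning("BLAST query id(s) absent from the FASTA: ",
            paste(orphans, collapse = ", "))
  hitResidues <- NULL
  if (!is.null(hitFasta)) {
    hrecs <- readQueries(hitFasta, alphabet = "protein")
    hitResidues <- stats::setNames(
      vapply(hrecs, function(r) r@residues, character(1)),
      vapply(hrecs, function(r) r@id, character(1)))
  }
  reports <- lapply(queries, function(q) {
    hits <- hitsMap[[q@id]]
    if (is.null(hits)) hits <- list()
    validateQuery(q, hits, config, hitResidues)
  })
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  inputs <- list(queries = basename(inputFasta),
                 blast = basename(blastOutput),
                 blast_format = blastFormat)
  files <- character()
  if ("json" %in% formats)
    files <- c(files, renderJson(reports, file.path(outputDir, "report.json"),
                                 config, inputs, timestamp))
  if ("tsv" %in% formats)
    files <- c(files, renderTsv(reports, file.path(outputDir, "report.tsv")))
  if ("html" %in% formats)
    files <- c(files, renderHtml(reports, file.path(outputDir, "report.html"),
                                 timestamp))
  if (!quiet) {
    st <- table(unlist(lapply(reports, function(r)
      paste(names(verdictStatuses(r)), verdictStatuses(r)))))
    message(length(reports), " quer(y/ies) validated; verdict counts:")
    for (nm in names(st)) message("  ", nm, ": ", st[[nm]])
  }
  invisible(list(reports = reports, files = files))
}
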