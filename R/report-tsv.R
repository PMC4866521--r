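TSV_VALIDATION_COLUMNS <- VALIDATION_NAMES

#' Write the TSV report
#'
#' Header row, then one row per query: query id, score (empty when
#' absent), hit count, and one status column per validation analysis (the
#' maker_qi column is empty when the defline carried no QI tag).  UTF-8,
#' LF line endings, no quoting.
#'
#' @param reports list of [QueryReport-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
renderTsv <- function(reports, path) {
  header <- paste(c("query_id", "score", "n_hits", TSV_VALIDATION_COLUMNS),
                  collapse = "\t")
  rows <- vapply(reports, function(r) {
    st <- verdictStatuses(r)
    cells <- vapply(TSV_VALIDATION_COLUMNS, function(nm)
      if (nm %in% names(st)) unname(st[nm]) else "", character(1))
    paste(c(r@queryId,
            if (is.na(r@score)) "" else as.character(r@score),
            as.character(r@nHits), cells), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a TSV report back as a data.frame
#'
#' @param path TSV report file.
#' @return data.frame with one row per query.
#' @export
readReportTsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character", check.names = FALSE)
}
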