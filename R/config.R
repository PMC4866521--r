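#' Analysis configuration
#'
#' All empirical cutoffs used by the validation analyses live in one flat
#' configuration object so they can be overridden together, from code or
#' from a plain-text `key=value` file.
#'
#' @param ... named overrides of the defaults listed below.
#' @return a named list of class `gv_config`.
#'
#' @details Defaults:
#' \describe{
#'   \item{topHits (10)}{hits entering each BLAST-based analysis, most
#'     significant first.}
#'   \item{maxHits (500)}{global per-query cap applied at parse time.}
#'   \item{ntFraction (0.9)}{fraction of A/C/G/T/U/N letters above which a
#'     sequence is called nucleotide.}
#'   \item{rankLow, rankHigh (0.2, 0.8)}{length rank cutoffs: below
#'     rankLow the query is flagged too short, above rankHigh too long.}
#'   \item{clusterGapMin (5), clusterGapFrac (0.1)}{single-linkage
#'     clustering of hit lengths stops merging when the smallest gap exceeds
#'     max(clusterGapMin, clusterGapFrac * median hit length) aa.}
#'   \item{lengthTolerance (0.1)}{relative slack around the main length
#'     cluster accepted for the query length.}
#'   \item{duplicationAlpha (0.05)}{Wilcoxon significance level for the
#'     coverage/duplication test.}
#'   \item{mergeSlopeLow, mergeSlopeHigh (0.4, 1.2)}{weighted-regression
#'     slope window flagging a merged (fused) gene model.}
#'   \item{minOrfLen (90)}{minimum ORF length in nt.}
#'   \item{majorOrfRatio (0.8)}{an ORF is "major" when at least this
#'     fraction of the longest ORF's length.}
#'   \item{orfSimilarityMin (0.8)}{minimum fraction of HSP-covered nt that
#'     must fall inside one ORF.}
#'   \item{conservedRunLen (5), conservedMaxFrac (0.2)}{minimum run length
#'     for a missing/extra region and the maximum tolerated total fraction
#'     of core profile columns.}
#'   \item{makerQiMin (0.8)}{minimum mean EST support fraction in the MAKER
#'     quality index.}
#'   \item{gapOpen (11), gapExtend (1)}{affine gap penalties (positive
#'     costs) used by all alignments, BLOSUM62 scoring.}
#'   \item{profileMaxSeqs (10)}{hit sequences entering the conserved-regions
#'     profile alignment.}
#' }
#' @examples
#' cfg <- gvConfig(topHits = 5)
#' cfg$topHits
#' @export
gvConfig <- function(...) {
  cfg <- list(
    topHits = 10L, maxHits = 500L, ntFraction = 0.9,
    rankLow = 0.2, rankHigh = 0.8,
    clusterGapMin = 5, clusterGapFrac = 0.1, lengthTolerance = 0.1,
    duplicationAlpha = 0.05,
    mergeSlopeLow = 0.4, mergeSlopeHigh = 1.2,
    minOrfLen = 90L, majorOrfRatio = 0.8, orfSimilarityMin = 0.8,
    conservedRunLen = 5L, conservedMaxFrac = 0.2,
    makerQiMin = 0.8,
    gapOpen = 11, gapExtend = 1, profileMaxSeqs = 10L)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad))
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    for (k in names(over)) {
      cfg[[k]] <- if (is.integer(cfg[[k]])) as.integer(over[[k]])
                  else as.numeric(over[[k]])
    }
  }
  structure(cfg, class = "gv_config")
}

#' Read a configuration file
#'
#' Plain-text `key=value` lines; blank lines and lines starting with `#`
#' are ignored.  Unknown keys are an error.
#'
#' @param path file path.
#' @return a `gv_config` list.
#' @export
readConfigFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(gvConfig())
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed config line: ", lines[which(bad)[1L]])
  vals <- lapply(kv, function(p) as.numeric(trimws(p[2L])))
  names(vals) <- vapply(kv, function(p) trimws(p[1L]), character(1))
  do.call(gvConfig, vals)
}

#' Write a configuration file
#'
#' @param config a `gv_config` list.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeConfigFile <- function(config, path) {
  stopifnot(inherits(config, "gv_config"))
  writeLines(sprintf("%s=%s", names(config),
                     vapply(config, format, character(1), digits = 15)),
             path)
  invisible(path)
}
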