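#' Combine verdicts into the 0-100 quality score
#'
#' The score is the percentage of passed analyses among those that reached
#' a pass/fail decision, rounded half-up to an integer; skipped and
#' errored analyses are excluded from both numerator and denominator so
#' protein and nucleotide queries remain comparable.  With no decided
#' analysis the score is absent (NA).
#'
#' @param verdicts list of [ValidationVerdict-class].
#' @return integer score in 0..100, or NA.
#' @examples
#' v <- list() # no decided analyses
#' combineScore(v) # NA
#' @export
combineScore <- function(verdicts) {
  st <- vapply(verdicts, function(v) v@status, character(1))
  nPass <- sum(st == "pass")
  nFail <- sum(st == "fail")
  if (nPass + nFail == 0L) return(NA_integer_)
  as.integer(floor(100 * nPass / (nPass + nFail) + 0.5))
}

#' Run every applicable validation on one query
#'
#' Executes the seven hit/sequence analyses (the two ORF analyses skip on
#' protein queries, the BLAST-based ones skip without hits) and, when the
#' defline carries a MAKER QI tag, the quality-index analysis.  A failure
#' inside one analysis is caught and recorded as an `error` verdict
#' without aborting the query.
#'
#' @param query a [SequenceRecord-class].
#' @param hits list of [BlastHit-class] paired with the query (may be
#'   empty).
#' @param config a [gvConfig()] list.
#' @param hitFasta optional named character vector of full hit residues
#'   for the conserved-regions profile.
#' @return a [QueryReport-class].
#' @export
validateQuery <- function(query, hits = list(), config = gvConfig(),
                          hitFasta = NULL) {
  stopifnot(is(query, "SequenceRecord"))
  safely <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .newVerdict(name, "error", message = conditionMessage(e)))
  }
  noHits <- function(name) .skip(name, "no hits")
  hasHits <- length(hits) > 0L
  verdicts <- list(
    safely("length_cluster",
           if (hasHits) validateLengthCluster(query, hits, config)
           else noHits("length_cluster")),
    safely("length_rank",
           if (hasHits) validateLengthRank(query, hits, config)
           else noHits("length_rank")),
    safely("duplication", validateDuplication(query, hits, config)),
    safely("conserved_regions",
           if (hasHits) validateConservedRegions(query, hits, config, hitFasta)
           else noHits("conserved_regions")),
    safely("gene_merge",
           if (hasHits) validateGeneMerge(query, hits, config)
           else noHits("gene_merge")),
    safely("orf_ab_initio", validateOrfAbInitio(query, config)),
    safely("orf_similarity", validateOrfSimilarity(query, hits, config)))
  if (grepl("(^|\\s)QI:", query@defline))
    verdicts <- c(verdicts, list(
      safely("maker_qi",
             validateMakerQI(query, parseMakerQI(query@defline), config))))
  new("QueryReport", queryId = query@id, nHits = length(hits),
      verdicts = verdicts, score = combineScore(verdicts))
}
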