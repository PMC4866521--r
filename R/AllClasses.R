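#' @import methods
NULL

VALIDATION_NAMES <- c("length_cluster", "length_rank", "duplication",
                      "conserved_regions", "gene_merge",
                      "orf_ab_initio", "orf_similarity", "maker_qi")

VERDICT_STATUSES <- c("pass", "fail", "unsure", "skipped", "error")

PLOT_KINDS <- c("length_histogram", "hsp_offsets", "hit_overview",
                "conserved_map", "orf_tracks")

HSP_COLUMNS <- c("qStart", "qEnd", "hStart", "hEnd", "qFrame",
                 "evalue", "evalueStr", "bitscore", "qAln", "hAln")

#' One query gene prediction
#'
#' Holds a single sequence from the query FASTA: the identifier (first
#' whitespace-delimited defline word), the full defline, the uppercased
#' residues and the detected alphabet.
#'
#' @slot id character(1) unique identifier.
#' @slot defline character(1) full header text (without the leading ">").
#' @slot residues character(1) uppercase residues.
#' @slot alphabet "protein" or "nucleotide".
#' @export
setClass("SequenceRecord",
  representation(id = "character", defline = "character",
                 residues = "character", alphabet = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@id) != 1L || !nzchar(object@id))
      msg <- c(msg, "id must be a non-empty string")
    if (length(object@residues) != 1L || !nzchar(object@residues))
      msg <- c(msg, "residues must be non-empty")
    if (!(object@alphabet %in% c("protein", "nucleotide")))
      msg <- c(msg, "alphabet must be 'protein' or 'nucleotide'")
    else {
      ok <- if (object@alphabet == "nucleotide")
        grepl("^[ACGTUNRYSWKMBDHV*X-]+$", object@residues)
      else
        grepl("^[ACDEFGHIKLMNPQRSTVWYXBZJUON*-]+$", object@residues)
      if (!ok) msg <- c(msg, sprintf(
        "residues of '%s' contain characters invalid for alphabet %s",
        object@id, object@alphabet))
    }
    if (length(msg)) msg else TRUE
  })

#' One BLAST hit with its HSPs
#'
#' A database subject sequence and its high-scoring segment pairs against
#' one query.  All coordinates are 0-based half-open; query-side coordinates
#' are in query residue units (aa for protein queries, nt for nucleotide
#' queries), hit-side coordinates in aa.  HSPs are sorted by ascending
#' e-value, ties broken by descending bitscore then ascending query start.
#'
#' @slot id character(1) subject identifier.
#' @slot description character(1) subject title (may be empty).
#' @slot length integer(1) full subject length in aa.
#' @slot hsps data.frame with columns qStart, qEnd, hStart, hEnd, qFrame,
#'   evalue, evalueStr, bitscore, qAln, hAln.
#' @export
setClass("BlastHit",
  representation(id = "character", description = "character",
                 length = "integer", hsps = "data.frame"),
  validity = function(object) {
    msg <- character()
    h <- object@hsps
    if (!all(HSP_COLUMNS %in% names(h)))
      return("hsps must have the full HSP column set")
    if (nrow(h) == 0L) msg <- c(msg, "a hit must have at least one HSP")
    if (any(h$qStart >= h$qEnd)) msg <- c(msg, "qStart must be < qEnd")
    if (any(h$hStart >= h$hEnd)) msg <- c(msg, "hStart must be < hEnd")
    if (any(h$hEnd > object@length))
      msg <- c(msg, "hEnd exceeds the hit length")
    if (any(h$evalue < 0)) msg <- c(msg, "evalue must be non-negative")
    if (any(h$bitscore <= 0)) msg <- c(msg, "bitscore must be positive")
    if (nrow(h) > 1L) {
      ord <- order(h$evalue, -h$bitscore, h$qStart)
      if (!identical(ord, seq_len(nrow(h))))
        msg <- c(msg, "hsps must be sorted by evalue, bitscore, qStart")
    }
    both <- !is.na(h$qAln) & !is.na(h$hAln)
    if (any(nchar(h$qAln[both]) != nchar(h$hAln[both])))
      msg <- c(msg, "aligned strings must have equal length")
    if (length(msg)) msg else TRUE
  })

#' Diagnostic plot payload
#'
#' Language-neutral description of one report graph: a kind (one of five),
#' named numeric series, and labelled annotation markers.  Rendered as
#' inline SVG by [renderHtml()].
#'
#' @slot kind one of length_histogram, hsp_offsets, hit_overview,
#'   conserved_map, orf_tracks.
#' @slot series named list of numeric vectors.
#' @slot annotations named list of scalar labels/values.
#' @export
setClass("PlotPayload",
  representation(kind = "character", series = "list", annotations = "list"),
  validity = function(object) {
    if (!(length(object@kind) == 1L && object@kind %in% PLOT_KINDS))
      return("kind must be one of the five plot kinds")
    TRUE
  })

#' Outcome of one validation analysis
#'
#' @slot name the analysis name (length_cluster, length_rank, duplication,
#'   conserved_regions, gene_merge, orf_ab_initio, orf_similarity, maker_qi).
#' @slot status pass, fail, unsure, skipped or error.
#' @slot statistic numeric(1) decision quantity (NA when not applicable).
#' @slot threshold numeric cutoff applied; length 2 when the cutoff is an
#'   accepted interval.
#' @slot pValue numeric(1) in [0,1] or NA.
#' @slot message one-line human explanation.
#' @slot plot a [PlotPayload-class] or NULL.
#' @export
setClass("ValidationVerdict",
  representation(name = "character", status = "character",
                 statistic = "numeric", threshold = "numeric",
                 pValue = "numeric", message = "character", plot = "ANY"),
  prototype(statistic = NA_real_, threshold = NA_real_, pValue = NA_real_,
            message = "", plot = NULL),
  validity = function(object) {
    msg <- character()
    if (!(object@name %in% VALIDATION_NAMES))
      msg <- c(msg, sprintf("unknown validation name '%s'", object@name))
    if (!(object@status %in% VERDICT_STATUSES))
      msg <- c(msg, sprintf("unknown status '%s'", object@status))
    if (object@status %in% c("pass", "fail")) {
      if (is.na(object@statistic))
        msg <- c(msg, "pass/fail verdicts must carry a statistic")
      if (all(is.na(object@threshold)))
        msg <- c(msg, "pass/fail verdicts must carry a threshold")
    }
    if (object@status == "skipped" && !nzchar(object@message))
      msg <- c(msg, "skipped verdicts must explain why")
    if (!is.na(object@pValue) &&
        (object@pValue < 0 || object@pValue > 1))
      msg <- c(msg, "pValue must lie in [0,1]")
    if (!is.null(object@plot) && !is(object@plot, "PlotPayload"))
      msg <- c(msg, "plot must be a PlotPayload or NULL")
    if (length(msg)) msg else TRUE
  })

#' All verdicts for one query plus the combined score
#'
#' @slot queryId character(1).
#' @slot nHits integer(1) number of BLAST hits paired with the query.
#' @slot verdicts list of [ValidationVerdict-class].
#' @slot score integer(1) in 0..100, or NA when no verdict was decided.
#' @export
setClass("QueryReport",
  representation(queryId = "character", nHits = "integer",
                 verdicts = "list", score = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nHits < 0L) msg <- c(msg, "nHits must be >= 0")
    if (!all(vapply(object@verdicts, is, logical(1), "ValidationVerdict")))
      msg <- c(msg, "verdicts must all be ValidationVerdict objects")
    decided <- sum(vapply(object@verdicts, function(v)
      v@status %in% c("pass", "fail"), logical(1)))
    if (decided == 0L && !is.na(object@score))
      msg <- c(msg, "score must be NA when no verdict is decided")
    if (decided > 0L && is.na(object@score))
      msg <- c(msg, "score must be set when a verdict is decided")
    if (!is.na(object@score) && (object@score < 0L || object@score > 100L))
      msg <- c(msg, "score must lie in [0, 100]")
    if (length(msg)) msg else TRUE
  })

#' Position-specific scoring profile of hit sequences
#'
#' Per-column residue + gap frequencies built from a multiple alignment of
#' at most ten hit sequences, with an add-one pseudocount over the 20 amino
#' acids.  Columns whose raw gap fraction exceeds 0.5 are flagged non-core.
#'
#' @slot freqs 21 x n matrix (rows: 20 aa then "-"); each column sums to 1.
#' @slot core logical(n), FALSE where the gap fraction exceeds 0.5.
#' @slot nSeqs integer(1) number of sequences used (2..10).
#' @export
setClass("GVProfile",
  representation(freqs = "matrix", core = "logical", nSeqs = "integer"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@freqs) != 21L)
      msg <- c(msg, "freqs must have 21 rows (20 aa + gap)")
    if (length(object@core) != ncol(object@freqs))
      msg <- c(msg, "core flag length must match the number of columns")
    if (object@nSeqs < 2L) msg <- c(msg, "a profile needs at least 2 sequences")
    if (ncol(object@freqs) > 0 &&
        any(abs(colSums(object@freqs) - 1) > 1e-9))
      msg <- c(msg, "column frequencies must sum to 1")
    if (length(msg)) msg else TRUE
  })

#' A fabricated test scenario
#'
#' A (query, BLAST tabular) pair with a known planted defect and the
#' expected verdict statuses for the diagnostic analyses.
#'
#' @slot kind one of clean, truncated, too_long, fused, duplicated,
#'   frameshifted, no_hits.
#' @slot seed integer(1) generator seed.
#' @slot query the [SequenceRecord-class] query.
#' @slot hitsTable character vector of BLAST tabular lines (may be empty).
#' @slot expectation named character: validation name -> expected status for
#'   the statuses the construction pins down.
#' @export
setClass("GVScenario",
  representation(kind = "character", seed = "integer",
                 query = "SequenceRecord", hitsTable = "character",
                 expectation = "character"),
  validity = function(object) {
    kinds <- c("clean", "truncated", "too_long", "fused", "duplicated",
               "frameshifted", "no_hits")
    if (!(object@kind %in% kinds)) return("unknown scenario kind")
    if (length(object@expectation) &&
        !all(names(object@expectation) %in% VALIDATION_NAMES))
      return("expectation names must be validation names")
    TRUE
  })

setMethod("show", "SequenceRecord", function(object) {
  cat(sprintf("SequenceRecord %s: %d %s residues\n", object@id,
              nchar(object@residues),
              if (object@alphabet == "protein") "aa" else "nt"))
})

setMethod("show", "BlastHit", function(object) {
  cat(sprintf("BlastHit %s: length %d aa, %d HSP(s), best e-value %g\n",
              object@id, object@length, nrow(object@hsps),
              min(object@hsps$evalue)))
})

setMethod("show", "ValidationVerdict", function(object) {
  cat(sprintf("[%s] %s  statistic=%s  %s\n", object@status, object@name,
              format(object@statistic, digits = 4), object@message))
})

setMethod("show", "QueryReport", function(object) {
  cat(sprintf("QueryReport %s: %d hit(s), score %s\n", object@queryId,
              object@nHits,
              if (is.na(object@score)) "NA" else object@score))
  for (v in object@verdicts) show(v)
})

setMethod("show", "GVScenario", function(object) {
  cat(sprintf("GVScenario '%s' (seed %d): query %s, %d BLAST row(s)\n",
              object@kind, object@seed, object@query@id,
              length(object@hitsTable)))
})
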