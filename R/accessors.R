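#' Accessors for genecheck S4 objects
#'
#' Small read-only accessors so user code never reaches into slots.
#'
#' @param x a genecheck S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("queryId", function(x) standardGeneric("queryId"))
#' @rdname accessors
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))
#' @rdname accessors
#' @export
setGeneric("alphabet", function(x) standardGeneric("alphabet"))
#' @rdname accessors
#' @export
setGeneric("hsps", function(x) standardGeneric("hsps"))
#' @rdname accessors
#' @export
setGeneric("bestEvalue", function(x) standardGeneric("bestEvalue"))
#' @rdname accessors
#' @export
setGeneric("verdicts", function(x) standardGeneric("verdicts"))
#' @rdname accessors
#' @export
setGeneric("verdictStatus", function(x) standardGeneric("verdictStatus"))
#' @rdname accessors
#' @export
setGeneric("statistic", function(x) standardGeneric("statistic"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("score", function(x) standardGeneric("score"))
#' @rdname accessors
#' @export
setGeneric("plotPayload", function(x) standardGeneric("plotPayload"))

#' @rdname accessors
setMethod("queryId", "SequenceRecord", function(x) x@id)
#' @rdname accessors
setMethod("queryId", "QueryReport", function(x) x@queryId)
#' @rdname accessors
setMethod("residues", "SequenceRecord", function(x) x@residues)
#' @rdname accessors
setMethod("alphabet", "SequenceRecord", function(x) x@alphabet)
#' @rdname accessors
setMethod("hsps", "BlastHit", function(x) x@hsps)
#' @rdname accessors
setMethod("bestEvalue", "BlastHit", function(x) min(x@hsps$evalue))
#' @rdname accessors
setMethod("verdicts", "QueryReport", function(x) x@verdicts)
#' @rdname accessors
setMethod("verdictStatus", "ValidationVerdict", function(x) x@status)
#' @rdname accessors
setMethod("statistic", "ValidationVerdict", function(x) x@statistic)
#' @rdname accessors
setMethod("pValue", "ValidationVerdict", function(x) x@pValue)
#' @rdname accessors
setMethod("score", "QueryReport", function(x) x@score)
#' @rdname accessors
setMethod("plotPayload", "ValidationVerdict", function(x) x@plot)

#' Verdict statuses of a report as a named character vector
#'
#' @param report a [QueryReport-class].
#' @return named character vector, names are validation names.
#' @export
verdictStatuses <- function(report) {
  stopifnot(is(report, "QueryReport"))
  vapply(report@verdicts, function(v) v@status, character(1),
         USE.NAMES = FALSE) |>
    stats::setNames(vapply(report@verdicts, function(v) v@name, character(1)))
}
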