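STOP_CODONS <- c("TAA", "TAG", "TGA")

.revComp <- function(nt) {
  x <- chartr("U", "T", toupper(nt))
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# maximal stop-free codon runs on one strand, offsets 0..2; returns a list
# of 2-column matrices of 0-based half-open intervals in strand coordinates
.scanStrand <- function(nt, minOrfLen) {
  L <- nchar(nt)
  lapply(0:2, function(off) {
    nCodon <- (L - off) %/% 3L
    if (nCodon == 0L)
      return(matrix(integer(), ncol = 2L,
                    dimnames = list(NULL, c("start", "end"))))
    starts <- off + 3L * (seq_len(nCodon) - 1L)
    codons <- substring(nt, starts + 1L, starts + 3L)
    isStop <- codons %in% STOP_CODONS
    bounds <- c(0L, which(isStop), nCodon + 1L)
    out <- matrix(integer(), ncol = 2L)
    for (b in seq_len(length(bounds) - 1L)) {
      from <- bounds[b] + 1L
      to <- bounds[b + 1L] - 1L
      if (to < from) next
      s <- starts[from]
      e <- starts[to] + 3L
      if (e - s >= minOrfLen) out <- rbind(out, c(s, e))
    }
    colnames(out) <- c("start", "end")
    out
  })
}

#' Scan a nucleotide sequence for open reading frames
#'
#' ORFs are maximal stop-free codon runs (stop codons TAA/TAG/TGA, standard
#' code) in each of the six reading frames, trimmed to codon boundaries;
#' sequence ends act as ORF boundaries (no start codon is required) and
#' runs shorter than `minOrfLen` nt are discarded.  All intervals are
#' reported as 0-based half-open coordinates on the plus strand.
#'
#' @param nt nucleotide string.
#' @param minOrfLen minimum ORF length in nt.
#' @return named list of class `orf_set` over frames `+1,+2,+3,-1,-2,-3`,
#'   each a 2-column matrix of (start, end) intervals.
#' @export
findOrfs <- function(nt, minOrfLen = 90L) {
  nt <- chartr("U", "T", toupper(nt))
  L <- nchar(nt)
  empty <- matrix(integer(), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  if (L < 3L)
    return(structure(stats::setNames(rep(list(empty), 6L), frames),
                     class = "orf_set"))
  plus <- .scanStrand(nt, minOrfLen)
  minus <- .scanStrand(.revComp(nt), minOrfLen)
  minus <- lapply(minus, function(m) {
    if (!nrow(m)) return(m)
    out <- cbind(start = L - m[, "end"], end = L - m[, "start"])
    out[order(out[, "start"]), , drop = FALSE]
  })
  structure(stats::setNames(c(plus, minus), frames), class = "orf_set")
}

# all ORFs of a set as one data.frame (frame, start, end, length)
.orfTable <- function(orfs) {
  rows <- lapply(names(orfs), function(f) {
    m <- orfs[[f]]
    if (!nrow(m)) return(NULL)
    data.frame(frame = f, start = m[, "start"], end = m[, "end"],
               length = m[, "end"] - m[, "start"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(frame = character(), start = integer(),
                      end = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# translate the longest ORF of a nucleotide query to protein
.translateLongestOrf <- function(nt, minOrfLen = 90L) {
  orfs <- .orfTable(findOrfs(nt, minOrfLen))
  if (!nrow(orfs)) return(NULL)
  top <- orfs[order(-orfs$length, orfs$start), ][1L, ]
  nt <- chartr("U", "T", toupper(nt))
  sub <- substr(nt, top$start + 1L, top$end)
  if (startsWith(top$frame, "-")) sub <- .revComp(sub)
  aa <- Biostrings::translate(Biostrings::DNAString(sub),
                              if.fuzzy.codon = "X")
  as.character(aa)
}
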