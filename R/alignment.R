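AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.blosumEnv <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.blosumEnv$B)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosumEnv$B <- e$BLOSUM62
  }
  .blosumEnv$B
}

# canonicalize rare ambiguity codes so every residue scores like a real aa
.canonResidues <- function(x) {
  chartr("JUO", "LCK", x)
}

.splitChars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Progressive multiple alignment of hit sequences
#'
#' Pairwise global alignments (BLOSUM62, gap open 11, extend 1) define a
#' distance of one minus fractional identity; the sequence with the
#' smallest average distance seeds the alignment and the others are
#' inserted in order of increasing distance to it, each aligned globally
#' against the growing alignment's residue-frequency profile with the same
#' scoring.
#'
#' @param seqs character vector of 2 to 10 protein sequences.
#' @param gapOpen,gapExtend positive affine gap costs.
#' @return character vector of equal-length gapped strings, same order as
#'   the input.
#' @export
multipleAlign <- function(seqs, gapOpen = 11, gapExtend = 1) {
  n <- length(seqs)
  if (n < 2L) stop("multiple alignment needs at least 2 sequences")
  if (n > 10L)
    stop("multiple alignment accepts at most 10 sequences (got ", n, ")")
  seqs <- toupper(seqs)
  if (any(grepl("-", seqs, fixed = TRUE)))
    stop("input sequences must be ungapped")
  canon <- .canonResidues(seqs)

  d <- matrix(0, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(canon[(i + 1L):n]),
        Biostrings::AAString(canon[i]),
        type = "global", substitutionMatrix = .blosum62(),
        gapOpening = gapOpen, gapExtension = gapExtend)
      dv <- 1 - Biostrings::pid(aln, type = "PID1") / 100
      d[i, (i + 1L):n] <- dv
      d[(i + 1L):n, i] <- dv
    }
  }
  centroid <- which.min(rowMeans(d))
  rest <- setdiff(seq_len(n), centroid)
  order_in <- c(centroid, rest[order(d[centroid, rest], rest)])

  B <- .blosum62()
  rows <- .splitChars(canon[order_in[1L]])
  alnRows <- list(matrix(rows, nrow = 1L))
  alnMat <- matrix(rows, nrow = 1L)
  for (k in order_in[-1L]) {
    s <- .splitChars(canon[k])
    m <- ncol(alnMat)
    # residue-frequency profile of the current alignment (gaps score 0)
    cnt <- vapply(seq_len(m), function(j) {
      col <- alnMat[, j]
      tabulate(match(col, AA20), nbins = 20L) +
        0.05 * sum(!(col %in% c(AA20, "-")))  # X spread uniformly
    }, numeric(20L))
    freq <- cnt / nrow(alnMat)                       # 20 x m
    S <- t(freq) %*% B[AA20, s, drop = FALSE]        # m x length(s)
    path <- c_affine_align(S, gapOpen, gapExtend)
    newCols <- nrow(path)
    out <- matrix("-", nrow = nrow(alnMat) + 1L, ncol = newCols)
    for (p in seq_len(newCols)) {
      pc <- path[p, 1L]; sp <- path[p, 2L]
      if (pc > 0L) out[seq_len(nrow(alnMat)), p] <- alnMat[, pc]
      if (sp > 0L) out[nrow(out), p] <- s[sp]
    }
    alnMat <- out
  }
  aligned <- apply(alnMat, 1L, paste, collapse = "")
  # restore original residues (undo canonicalisation) and input order
  res <- character(n)
  for (idx in seq_along(order_in)) {
    orig <- .splitChars(seqs[order_in[idx]])
    chars <- .splitChars(aligned[idx])
    chars[chars != "-"] <- orig
    res[order_in[idx]] <- paste(chars, collapse = "")
  }
  res
}

#' Build a position-specific scoring profile
#'
#' Per-column residue and gap frequencies from an alignment of 2 to 10 hit
#' sequences, with an add-one pseudocount over the 20 amino acids; columns
#' whose raw gap fraction exceeds one half are flagged non-core.
#'
#' @param alignedRows character vector of equal-length gapped sequences.
#' @return a [GVProfile-class].
#' @export
buildProfile <- function(alignedRows) {
  n <- length(alignedRows)
  if (n < 2L) stop("a profile needs at least 2 sequences")
  if (n > 10L) stop("a profile uses at most 10 sequences (got ", n, ")")
  lens <- nchar(alignedRows)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences must have equal length")
  rows <- .canonResidues(toupper(alignedRows))
  mat <- do.call(rbind, lapply(rows, .splitChars))
  m <- ncol(mat)
  freqs <- matrix(0, nrow = 21L, ncol = m,
                  dimnames = list(c(AA20, "-"), NULL))
  gapFrac <- numeric(m)
  for (j in seq_len(m)) {
    col <- mat[, j]
    cnt <- tabulate(match(col, AA20), nbins = 20L)
    nx <- sum(!(col %in% c(AA20, "-")))
    cnt <- cnt + nx / 20          # ambiguous residues spread uniformly
    ngap <- sum(col == "-")
    gapFrac[j] <- ngap / n
    freqs[seq_len(20L), j] <- (cnt + 1) / (n + 20)
    freqs[21L, j] <- ngap / (n + 20)
  }
  new("GVProfile", freqs = freqs, core = gapFrac <= 0.5,
      nSeqs = as.integer(n))
}

#' Align a query sequence to a profile
#'
#' Global profile-sequence alignment scored by the log-odds (base 2) of the
#' column residue frequency against a uniform 1/20 background, with the
#' package's affine gap costs.
#'
#' @param profile a [GVProfile-class].
#' @param residues ungapped protein string.
#' @param gapOpen,gapExtend positive affine gap costs.
#' @return integer matrix with columns (profile column, query position),
#'   1-based; 0 marks a gap on that side.
#' @export
alignToProfile <- function(profile, residues, gapOpen = 11, gapExtend = 1) {
  stopifnot(is(profile, "GVProfile"))
  s <- .splitChars(.canonResidues(toupper(residues)))
  logOdds <- log2(profile@freqs[seq_len(20L), , drop = FALSE] * 20)
  idx <- match(s, AA20)
  S <- matrix(0, nrow = ncol(profile@freqs), ncol = length(s))
  known <- !is.na(idx)
  if (any(known))
    S[, known] <- t(logOdds)[, idx[known], drop = FALSE]
  c_affine_align(S, gapOpen, gapExtend)
}
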