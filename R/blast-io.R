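DEFAULT_TABULAR_COLUMNS <-
  "qseqid sseqid evalue bitscore qstart qend sstart send slen qframe qseq sseq"

MANDATORY_COLUMNS <- c("qseqid", "sseqid", "evalue", "bitscore",
                       "qstart", "qend", "sstart", "send", "slen")

NT_CHARS   <- c("A", "C", "G", "T", "U", "N")
NT_ALL     <- c(NT_CHARS, strsplit("RYSWKMBDHV*X-", "")[[1]])
AA_ALL     <- strsplit("ACDEFGHIKLMNPQRSTVWYXBZJUON*-", "")[[1]]

#' Detect the alphabet of a sequence
#'
#' A sequence is called nucleotide when at least `ntFraction` (default 0.9)
#' of its non-gap characters are A, C, G, T, U or N; otherwise protein.
#'
#' @param residues uppercase residue string.
#' @param ntFraction fraction threshold for the nucleotide call.
#' @return "protein" or "nucleotide".
#' @examples
#' detectAlphabet("ACGTACGT")  # nucleotide
#' detectAlphabet("MKVLW")     # protein
#' @export
detectAlphabet <- function(residues, ntFraction = 0.9) {
  stopifnot(is.character(residues), length(residues) == 1L, nzchar(residues))
  chars <- strsplit(toupper(residues), "")[[1]]
  chars <- chars[chars != "-"]
  bad <- setdiff(unique(chars), union(NT_ALL, AA_ALL))
  if (length(bad))
    stop("invalid sequence character(s): ", paste(bad, collapse = ", "))
  if (mean(chars %in% NT_CHARS) >= ntFraction) "nucleotide" else "protein"
}

#' Read query gene predictions from FASTA
#'
#' Reads a (possibly gzip-compressed) FASTA file into a list of
#' [SequenceRecord-class] objects, preserving input order.  The alphabet is
#' auto-detected per sequence and must be homogeneous across the file
#' unless forced with `alphabet`.
#'
#' @param path FASTA file of protein or nucleotide predictions.
#' @param alphabet NULL for auto-detection, or "protein"/"nucleotide" to
#'   force.
#' @return list of [SequenceRecord-class], one per FASTA record.
#' @export
readQueries <- function(path, alphabet = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  first <- readLines(gzfile(path), n = 50L, warn = FALSE)
  nonblank <- which(nzchar(trimws(first)))
  if (!length(nonblank)) stop("no sequences in '", path, "'")
  if (!startsWith(trimws(first[nonblank[1L]]), ">"))
    stop("not a FASTA file: line ", nonblank[1L], " of '", path,
         "' does not start with '>'")
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in '", path, "'")
  deflines <- names(seqs)
  ids <- vapply(strsplit(deflines, "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  resv <- unname(toupper(as.character(seqs)))
  if (any(!nzchar(resv)))
    stop("empty sequence for id ", ids[which(!nzchar(resv))[1L]])
  alph <- if (is.null(alphabet)) {
    per <- vapply(resv, detectAlphabet, character(1), USE.NAMES = FALSE)
    if (length(unique(per)) > 1L)
      stop("mixed alphabets in one file (",
           paste(sprintf("%s:%s", ids, per), collapse = ", "),
           "); force one with the alphabet option")
    per[1L]
  } else match.arg(alphabet, c("protein", "nucleotide"))
  lapply(seq_along(ids), function(i)
    new("SequenceRecord", id = ids[i], defline = deflines[i],
        residues = resv[i], alphabet = alph))
}

#' Parse the MAKER quality index from a defline
#'
#' MAKER annotates predictions with a nine-field `QI:` defline tag
#' summarising evidence support: 5' UTR length, fraction of splice sites
#' confirmed by EST alignment, fraction of exons matching an EST, fraction
#' of exons matching any evidence, fractions of splice sites/exons
#' confirmed ab initio, exon count, 3' UTR length, protein length.  A value
#' of -1 encodes "not available".
#'
#' @param defline full FASTA defline text.
#' @return a named list of the nine values (class `maker_qi`), or NULL when
#'   the defline carries no parsable QI tag.  A malformed tag raises a
#'   warning and returns NULL.
#' @examples
#' parseMakerQI("g1 AED:0.05 QI:0|0.77|0.68|1|0.77|0.78|5|462|824")
#' @export
parseMakerQI <- function(defline) {
  tokens <- strsplit(defline, "\\s+")[[1]]
  tok <- grep("^QI:", tokens, value = TRUE)
  if (!length(tok)) return(NULL)
  fields <- strsplit(sub("^QI:", "", tok[1L]), "|", fixed = TRUE)[[1]]
  vals <- suppressWarnings(as.numeric(fields))
  if (length(fields) != 9L || anyNA(vals)) {
    warning("malformed MAKER QI tag ignored: ", tok[1L])
    return(NULL)
  }
  structure(as.list(vals),
            names = c("utr5_len", "splice_est_frac", "exon_est_frac",
                      "exon_evidence_frac", "splice_ab_frac",
                      "exon_ab_frac", "n_exons", "utr3_len", "protein_len"),
            class = "maker_qi")
}

#' Normalize BLAST query coordinates
#'
#' BLAST reports 1-based inclusive coordinates, and blastx minus-strand
#' HSPs may have start > end.  Internally every interval is 0-based
#' half-open and ascending on the plus strand; the frame sign is kept
#' separately.
#'
#' @param rawStart,rawEnd 1-based positions as printed by BLAST.
#' @param frame integer in -3..3 (0 for protein queries).
#' @param qlen query length in query units, or NA to skip the range check.
#' @return list(qStart, qEnd) 0-based half-open.
#' @export
normalizeHspCoords <- function(rawStart, rawEnd, frame = 0L, qlen = NA) {
  if (rawStart < 1L || rawEnd < 1L)
    stop("BLAST coordinates are 1-based; got (", rawStart, ", ", rawEnd, ")")
  lo <- min(rawStart, rawEnd)
  hi <- max(rawStart, rawEnd)
  if (!is.na(qlen) && hi > qlen)
    stop("HSP coordinate ", hi, " exceeds query length ", qlen)
  list(qStart = lo - 1L, qEnd = hi)
}

.emptyHsps <- function() {
  data.frame(qStart = integer(), qEnd = integer(), hStart = integer(),
             hEnd = integer(), qFrame = integer(), evalue = numeric(),
             evalueStr = character(), bitscore = numeric(),
             qAln = character(), hAln = character(),
             stringsAsFactors = FALSE)
}

.makeHit <- function(id, description, length, hsps) {
  ord <- order(hsps$evalue, -hsps$bitscore, hsps$qStart)
  hsps <- hsps[ord, , drop = FALSE]
  rownames(hsps) <- NULL
  new("BlastHit", id = id, description = description,
      length = as.integer(length), hsps = hsps)
}

.sortHits <- function(hits) {
  if (length(hits) <= 1L) return(hits)
  hits[order(vapply(hits, bestEvalue, numeric(1)),
             -vapply(hits, function(h) max(h@hsps$bitscore), numeric(1)))]
}

#' Parse tabular BLAST output (outfmt 6/7)
#'
#' Rows are grouped by query id then subject id into [BlastHit-class]
#' objects; hits are sorted per query by best e-value and all coordinates
#' are normalized to 0-based half-open.  Comment lines (`#`, outfmt 7) are
#' skipped.  The file may be gzip-compressed.
#'
#' @param path BLAST tabular file.
#' @param columns space-separated column names in file order; must include
#'   qseqid, sseqid, evalue, bitscore, qstart, qend, sstart, send and slen.
#'   Recognised optional columns: qframe, qseq, sseq, qlen, stitle.
#' @param maxHits per-query cap on the number of hits kept (by best
#'   e-value).
#' @return named list: query id -> list of [BlastHit-class].
#' @export
parseBlastTabular <- function(path, columns = DEFAULT_TABULAR_COLUMNS,
                              maxHits = 500L) {
  cols <- strsplit(trimws(columns), "\\s+")[[1]]
  missing <- setdiff(MANDATORY_COLUMNS, cols)
  if (length(missing))
    stop("tabular column set lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  lines <- readLines(gzfile(path), warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  if (!any(keep)) return(structure(list(), names = character()))
  lineNo <- which(keep)
  rows <- lapply(lines[keep], function(l) {
    if (grepl("\t", l, fixed = TRUE)) strsplit(l, "\t", fixed = TRUE)[[1]]
    else strsplit(trimws(l), "\\s+")[[1]]
  })
  nf <- lengths(rows)
  if (any(nf < length(cols)))
    stop("line ", lineNo[which(nf < length(cols))[1L]],
         ": expected ", length(cols), " fields, found ",
         nf[which(nf < length(cols))[1L]])
  if (any(nf > length(cols))) {
    if (cols[length(cols)] == "stitle") {
      rows <- lapply(rows, function(r) {
        c(r[seq_len(length(cols) - 1L)],
          paste(r[length(cols):length(r)], collapse = " "))
      })
    } else {
      stop("line ", lineNo[which(nf > length(cols))[1L]],
           ": more fields than declared columns")
    }
  }
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- cols
  has <- function(x) x %in% cols
  qframe <- if (has("qframe")) as.integer(tab$qframe) else
    rep(0L, nrow(tab))
  qlen <- if (has("qlen")) as.numeric(tab$qlen) else rep(NA_real_, nrow(tab))
  out <- list()
  for (qid in unique(tab$qseqid)) {
    sel <- which(tab$qseqid == qid)
    hits <- list()
    for (sid in unique(tab$sseqid[sel])) {
      rs <- sel[tab$sseqid[sel] == sid]
      hs <- .emptyHsps()
      for (i in rs) {
        q <- normalizeHspCoords(as.numeric(tab$qstart[i]),
                                as.numeric(tab$qend[i]),
                                qframe[i], qlen[i])
        h <- normalizeHspCoords(as.numeric(tab$sstart[i]),
                                as.numeric(tab$send[i]))
        hs <- rbind(hs, data.frame(
          qStart = as.integer(q$qStart), qEnd = as.integer(q$qEnd),
          hStart = as.integer(h$qStart), hEnd = as.integer(h$qEnd),
          qFrame = qframe[i],
          evalue = as.numeric(tab$evalue[i]), evalueStr = tab$evalue[i],
          bitscore = as.numeric(tab$bitscore[i]),
          qAln = if (has("qseq")) tab$qseq[i] else NA_character_,
          hAln = if (has("sseq")) tab$sseq[i] else NA_character_,
          stringsAsFactors = FALSE))
      }
      hits[[length(hits) + 1L]] <- .makeHit(
        sid, if (has("stitle")) tab$stitle[rs[1L]] else "",
        as.numeric(tab$slen[rs[1L]]), hs)
    }
    hits <- .sortHits(hits)
    if (length(hits) > maxHits) hits <- hits[seq_len(maxHits)]
    out[[qid]] <- hits
  }
  out
}

#' Write hits back to BLAST tabular format
#'
#' Inverse of [parseBlastTabular()] for the default column set: coordinates
#' are converted back to 1-based inclusive and e-values are written from
#' the preserved input strings, so a parse/write/parse round trip is exact.
#'
#' @param hitsMap named list (query id -> list of [BlastHit-class]).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeBlastTabular <- function(hitsMap, path) {
  lines <- character()
  for (qid in names(hitsMap)) {
    for (hit in hitsMap[[qid]]) {
      h <- hit@hsps
      lines <- c(lines, sprintf(
        "%s\t%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%s",
        qid, hit@id, h$evalueStr,
        vapply(h$bitscore, format, character(1), digits = 15),
        h$qStart + 1L, h$qEnd, h$hStart + 1L, h$hEnd,
        hit@length, h$qFrame,
        ifelse(is.na(h$qAln), "-", h$qAln),
        ifelse(is.na(h$hAln), "-", h$hAln)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse NCBI BLAST XML output
#'
#' Accepts single- or multi-query blastp/blastx XML and returns the same
#' structure as [parseBlastTabular()], with aligned strings taken from the
#' HSP alignment blocks and hit lengths from `Hit_len`.
#'
#' @param path BLAST XML file (plain or gzip-compressed).
#' @param maxHits per-query cap on the number of hits kept.
#' @return named list: query id -> list of [BlastHit-class].
#' @export
parseBlastXml <- function(path, maxHits = 500L) {
  doc <- xml2::read_xml(path)
  program <- xml2::xml_text(xml2::xml_find_first(doc, ".//BlastOutput_program"))
  if (!(program %in% c("blastp", "blastx")))
    stop("unsupported BLAST program '", program, "' (need blastp or blastx)")
  out <- list()
  for (iter in xml2::xml_find_all(doc, ".//Iteration")) {
    qdef <- xml2::xml_text(xml2::xml_find_first(iter, ".//Iteration_query-def"))
    if (is.na(qdef) || !nzchar(qdef))
      qdef <- xml2::xml_text(xml2::xml_find_first(doc, ".//BlastOutput_query-def"))
    qid <- strsplit(qdef, "\\s+")[[1]][1L]
    qlen <- as.numeric(xml2::xml_text(
      xml2::xml_find_first(iter, ".//Iteration_query-len")))
    hits <- list()
    for (hx in xml2::xml_find_all(iter, ".//Hit")) {
      t1 <- function(xp) xml2::xml_text(xml2::xml_find_first(hx, xp))
      hid <- t1(".//Hit_id")
      hdef <- t1(".//Hit_def")
      if (grepl("^(gnl\\|BL_ORD_ID|lcl\\|)", hid) || startsWith(hid, "Query_"))
        hid <- strsplit(hdef, "\\s+")[[1]][1L]
      hlen <- as.integer(t1(".//Hit_len"))
      hs <- .emptyHsps()
      for (px in xml2::xml_find_all(hx, ".//Hsp")) {
        p1 <- function(xp) xml2::xml_text(xml2::xml_find_first(px, xp))
        frame <- suppressWarnings(as.integer(p1(".//Hsp_query-frame")))
        if (is.na(frame)) frame <- 0L
        if (program == "blastp") frame <- 0L
        q <- normalizeHspCoords(as.numeric(p1(".//Hsp_query-from")),
                                as.numeric(p1(".//Hsp_query-to")),
                                frame, qlen)
        h <- normalizeHspCoords(as.numeric(p1(".//Hsp_hit-from")),
                                as.numeric(p1(".//Hsp_hit-to")))
        ev <- p1(".//Hsp_evalue")
        hs <- rbind(hs, data.frame(
          qStart = as.integer(q$qStart), qEnd = as.integer(q$qEnd),
          hStart = as.integer(h$qStart), hEnd = as.integer(h$qEnd),
          qFrame = frame,
          evalue = as.numeric(ev), evalueStr = ev,
          bitscore = as.numeric(p1(".//Hsp_bit-score")),
          qAln = p1(".//Hsp_qseq"), hAln = p1(".//Hsp_hseq"),
          stringsAsFactors = FALSE))
      }
      if (nrow(hs)) hits[[length(hits) + 1L]] <- .makeHit(hid, hdef, hlen, hs)
    }
    hits <- .sortHits(hits)
    if (length(hits) > maxHits) hits <- hits[seq_len(maxHits)]
    out[[qid]] <- hits
  }
  out
}

#' Recover hit sequences for profile building
#'
#' Hit residues come from a hit FASTA when provided; otherwise from the
#' ungapped aligned subject string of the hit's most significant HSP (which
#' requires the sseq tabular column or XML alignment blocks).
#'
#' @param hits list of [BlastHit-class].
#' @param hitFasta optional named character vector of full hit residues.
#' @return character vector (NA where unavailable), named by hit id.
#' @export
hitSequences <- function(hits, hitFasta = NULL) {
  vapply(hits, function(h) {
    if (!is.null(hitFasta) && h@id %in% names(hitFasta))
      return(toupper(hitFasta[[h@id]]))
    aln <- h@hsps$hAln[1L]
    if (is.na(aln) || !nzchar(aln)) return(NA_character_)
    gsub("-", "", toupper(aln), fixed = TRUE)
  }, character(1)) |> stats::setNames(vapply(hits, function(h) h@id,
                                             character(1)))
}
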