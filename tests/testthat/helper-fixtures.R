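# in-code fixture builders shared across test files

hspRow <- function(qStart, qEnd, hStart, hEnd, evalue = 1e-50,
                   bitscore = 200, qFrame = 0L,
                   qAln = NA_character_, hAln = NA_character_) {
  data.frame(qStart = as.integer(qStart), qEnd = as.integer(qEnd),
             hStart = as.integer(hStart), hEnd = as.integer(hEnd),
             qFrame = as.integer(qFrame), evalue = evalue,
             evalueStr = sprintf("%.3e", evalue), bitscore = bitscore,
             qAln = qAln, hAln = hAln, stringsAsFactors = FALSE)
}

testHit <- function(id, len, hsps) {
  hsps <- hsps[order(hsps$evalue, -hsps$bitscore, hsps$qStart), ,
               drop = FALSE]
  rownames(hsps) <- NULL
  new("BlastHit", id = id, description = "", length = as.integer(len),
      hsps = hsps)
}

# n hits of the given lengths, each with one full-span HSP and distinct
# e-values (most significant first)
hitsOfLengths <- function(lens, qlen = min(lens)) {
  lapply(seq_along(lens), function(i)
    testHit(sprintf("h%02d", i), lens[i],
            hspRow(0L, qlen, 0L, min(lens[i], qlen),
                   evalue = 10^(-80 + i), bitscore = 300 - i)))
}

protRecord <- function(res, id = "q1", defline = id) {
  new("SequenceRecord", id = id, defline = defline, residues = res,
      alphabet = "protein")
}

ntRecord <- function(res, id = "q1", defline = id) {
  new("SequenceRecord", id = id, defline = defline, residues = res,
      alphabet = "nucleotide")
}

# brute-force one-sided (greater) signed-rank p-value by enumerating all
# sign assignments; independent of the package implementation
bruteSignedRankP <- function(values, mu = 1) {
  d <- values - mu
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 12)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- signs %*% r
  mean(Ws >= W - 1e-12)
}

# closed-form weighted least squares slope/intercept (normal equations)
closedFormWls <- function(x, y, w) {
  xb <- sum(w * x) / sum(w)
  yb <- sum(w * y) / sum(w)
  slope <- sum(w * (x - xb) * (y - yb)) / sum(w * (x - xb)^2)
  list(slope = slope, intercept = yb - slope * xb)
}

# minimal NCBI BLAST XML document for given hits of one query
blastXmlDoc <- function(qid, qlen, hits, program = "blastp") {
  hitBlocks <- vapply(seq_along(hits), function(i) {
    h <- hits[[i]]
    hspBlocks <- vapply(seq_len(nrow(h@hsps)), function(k) {
      r <- h@hsps[k, ]
      qf <- r$qStart + 1L; qt <- r$qEnd
      if (r$qFrame < 0L) { tmp <- qf; qf <- qt; qt <- tmp }
      sprintf(paste0(
        "<Hsp><Hsp_num>%d</Hsp_num><Hsp_bit-score>%s</Hsp_bit-score>",
        "<Hsp_evalue>%s</Hsp_evalue>",
        "<Hsp_query-from>%d</Hsp_query-from><Hsp_query-to>%d</Hsp_query-to>",
        "<Hsp_hit-from>%d</Hsp_hit-from><Hsp_hit-to>%d</Hsp_hit-to>",
        "<Hsp_query-frame>%d</Hsp_query-frame>",
        "<Hsp_qseq>%s</Hsp_qseq><Hsp_hseq>%s</Hsp_hseq></Hsp>"),
        k, format(r$bitscore), r$evalueStr, qf, qt,
        r$hStart + 1L, r$hEnd, r$qFrame,
        ifelse(is.na(r$qAln), "", r$qAln),
        ifelse(is.na(r$hAln), "", r$hAln))
    }, character(1))
    sprintf(paste0(
      "<Hit><Hit_num>%d</Hit_num><Hit_id>%s</Hit_id>",
      "<Hit_def>%s</Hit_def><Hit_len>%d</Hit_len>",
      "<Hit_hsps>%s</Hit_hsps></Hit>"),
      i, h@id, ifelse(nzchar(h@description), h@description, h@id),
      h@length, paste(hspBlocks, collapse = ""))
  }, character(1))
  paste0(
    "<?xml version=\"1.0\"?>\n",
    "<BlastOutput><BlastOutput_program>", program,
    "</BlastOutput_program><BlastOutput_query-def>", qid,
    "</BlastOutput_query-def><BlastOutput_iterations>",
    "<Iteration><Iteration_iter-num>1</Iteration_iter-num>",
    "<Iteration_query-def>", qid, "</Iteration_query-def>",
    "<Iteration_query-len>", qlen, "</Iteration_query-len>",
    "<Iteration_hits>", paste(hitBlocks, collapse = ""),
    "</Iteration_hits></Iteration>",
    "</BlastOutput_iterations></BlastOutput>")
}
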