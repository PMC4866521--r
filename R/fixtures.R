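SCENARIO_KINDS <- c("clean", "truncated", "too_long", "fused", "duplicated",
                    "frameshifted", "no_hits")

# evaluate expr under a local seed without disturbing the caller's RNG
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Fabricate a protein family by i.i.d. substitution
#'
#' An ancestor of `lengthAA` residues is drawn uniformly over the 20 amino
#' acids; each member substitutes every site independently with
#' probability `divergence`, drawing the replacement uniformly over the 20
#' amino acids.  Deterministic per seed.
#'
#' @param seed integer seed.
#' @param lengthAA family sequence length (aa).
#' @param nMembers number of members (>= 2).
#' @param divergence per-site substitution rate in [0, 0.3].
#' @return character vector of `nMembers` protein strings.
#' @export
makeFamily <- function(seed, lengthAA, nMembers, divergence) {
  stopifnot(nMembers >= 2L, divergence >= 0, divergence <= 0.3)
  .withSeed(seed, {
    anc <- sample(AA20, lengthAA, replace = TRUE)
    vapply(seq_len(nMembers), function(i) {
      m <- anc
      hit <- stats::runif(lengthAA) < divergence
      if (any(hit)) m[hit] <- sample(AA20, sum(hit), replace = TRUE)
      paste(m, collapse = "")
    }, character(1))
  })
}

# per-column majority consensus of equal-length sequences
.consensus <- function(members) {
  mat <- do.call(rbind, lapply(members, .splitChars))
  paste(apply(mat, 2L, function(col)
    names(sort(table(col), decreasing = TRUE))[1L]), collapse = "")
}

# one deterministic sense codon per amino acid (chosen so that the
# frameshift construction can plant stop codons across codon boundaries:
# L ends in TA, K starts with AA)
CANONICAL_CODON <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
                     Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
                     L = "CTA", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
                     S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

.backTranslate <- function(aa) {
  paste(CANONICAL_CODON[.splitChars(aa)], collapse = "")
}

.fmtEvalue <- function(e) sprintf("%.3e", e)

# one tabular row in the package's default column layout
.tabRow <- function(qid, sid, evalue, bitscore, qstart, qend, sstart, send,
                    slen, qframe, qseq, sseq) {
  stopifnot(nchar(qseq) == nchar(sseq))
  paste(qid, sid, .fmtEvalue(evalue), bitscore, qstart, qend, sstart, send,
        slen, qframe, qseq, sseq, sep = "\t")
}

.logUniformEvalues <- function(n) sort(10^stats::runif(n, -100, -20))

#' Fabricate a (query, BLAST tabular) scenario with a planted defect
#'
#' Deterministically builds a query sequence and an internally consistent
#' BLAST tabular table exercising the validation analyses without running
#' BLAST:
#' \describe{
#'   \item{clean}{query is the consensus of a 10-member family (divergence
#'     0.1, 200 aa); each member is one full-span hit.  With
#'     `alphabet = "nucleotide"` the query is a stop-free back-translation
#'     and the table is blastx-style.}
#'   \item{truncated}{clean query with the C-terminal half removed; HSPs
#'     clipped to the remaining region.}
#'   \item{too_long}{clean query with an 80\% random-sequence C-terminal
#'     extension; hits unchanged.}
#'   \item{fused}{concatenation of two unrelated families' consensi
#'     (300 aa each); each family contributes ten HSPs to its own half,
#'     giving bimodal HSP coordinates with a start-stop regression slope
#'     near one.}
#'   \item{duplicated}{query with the C-terminal 40\% repeated in tandem;
#'     each hit has a gapped full-span HSP plus a second HSP mapping the
#'     extra copy onto the same hit region, so pooled hit coverage
#'     exceeds one.}
#'   \item{frameshifted}{nucleotide back-translation of the clean query
#'     with one inserted base at the midpoint; stop codons are planted at
#'     the codon boundaries flanking the insertion so the two halves fall
#'     into different reading frames, and the HSPs split across frames +1
#'     and +2.}
#'   \item{no_hits}{clean query with an empty BLAST table.}
#' }
#' E-values are log-uniform on [1e-100, 1e-20]; bitscores decrease with
#' e-value rank.  The expectation slot records the verdict statuses the
#' construction pins down.
#'
#' @param kind scenario kind (see above).
#' @param seed integer seed; regeneration with the same (kind, seed) is
#'   identical.
#' @param alphabet "protein" (default) or "nucleotide"; only the clean
#'   kind supports both (frameshifted is always nucleotide, the others
#'   protein).
#' @param withQI add a passing MAKER QI tag to the query defline.
#' @return a [GVScenario-class].
#' @export
makeScenario <- function(kind, seed, alphabet = "protein", withQI = FALSE) {
  kind <- match.arg(kind, SCENARIO_KINDS)
  seed <- as.integer(seed)
  .withSeed(seed + 7919L * match(kind, SCENARIO_KINDS), {
    members <- makeFamily(seed, 200L, 10L, 0.1)
    cons <- .consensus(members)
    qid <- paste0("q_", kind)
    defl <- function(id) if (withQI)
      paste0(id, " QI:0|1|1|1|0.5|0.5|4|0|", nchar(cons)) else id
    ev <- .logUniformEvalues(10L)
    bits <- round(400 - 2 * seq_along(ev))
    protRec <- function(res) new("SequenceRecord", id = qid,
                                 defline = defl(qid), residues = res,
                                 alphabet = "protein")
    expectation <- c()
    rows <- character()

    if (kind == "clean" && alphabet == "nucleotide") {
      nt <- .backTranslate(cons)
      query <- new("SequenceRecord", id = qid, defline = defl(qid),
                   residues = nt, alphabet = "nucleotide")
      rows <- vapply(seq_along(members), function(i)
        .tabRow(qid, sprintf("h%02d", i), ev[i], bits[i],
                1L, nchar(nt), 1L, 200L, 200L, 1L, cons, members[i]),
        character(1))
      expectation <- c(length_cluster = "pass", length_rank = "pass",
                       duplication = "pass", conserved_regions = "pass",
                       gene_merge = "pass", orf_ab_initio = "pass",
                       orf_similarity = "pass")
    } else if (kind == "clean") {
      query <- protRec(cons)
      rows <- vapply(seq_along(members), function(i)
        .tabRow(qid, sprintf("h%02d", i), ev[i], bits[i],
                1L, 200L, 1L, 200L, 200L, 0L, cons, members[i]),
        character(1))
      expectation <- c(length_cluster = "pass", length_rank = "pass",
                       duplication = "pass", conserved_regions = "pass",
                       gene_merge = "pass", orf_ab_initio = "skipped",
                       orf_similarity = "skipped")
    } else if (kind == "no_hits") {
      query <- protRec(cons)
      expectation <- c(length_cluster = "skipped", length_rank = "skipped",
                       duplication = "skipped",
                       conserved_regions = "skipped",
                       gene_merge = "skipped", orf_ab_initio = "skipped",
                       orf_similarity = "skipped")
    } else if (kind == "truncated") {
      query <- protRec(substr(cons, 1L, 100L))
      rows <- vapply(seq_along(members), function(i)
        .tabRow(qid, sprintf("h%02d", i), ev[i], bits[i],
                1L, 100L, 1L, 100L, 200L, 0L,
                substr(cons, 1L, 100L), substr(members[i], 1L, 100L)),
        character(1))
      expectation <- c(length_cluster = "fail", length_rank = "fail",
                       duplication = "pass", gene_merge = "pass")
    } else if (kind == "too_long") {
      ext <- paste(sample(AA20, 160L, replace = TRUE), collapse = "")
      query <- protRec(paste0(cons, ext))
      rows <- vapply(seq_along(members), function(i)
        .tabRow(qid, sprintf("h%02d", i), ev[i], bits[i],
                1L, 200L, 1L, 200L, 200L, 0L, cons, members[i]),
        character(1))
      expectation <- c(length_cluster = "fail", length_rank = "fail",
                       duplication = "pass", conserved_regions = "fail",
                       gene_merge = "pass")
    } else if (kind == "fused") {
      famA <- makeFamily(seed + 1L, 300L, 10L, 0.1)
      famB <- makeFamily(seed + 2L, 300L, 10L, 0.1)
      consA <- .consensus(famA); consB <- .consensus(famB)
      query <- protRec(paste0(consA, consB))
      ev20 <- .logUniformEvalues(20L)
      shuffled <- sample(ev20)       # interleave family significance
      bits20 <- round(400 - 2 * rank(shuffled))
      jit <- function(n, lo, hi) floor(stats::runif(n, lo, hi + 1))
      aS <- jit(10L, 1, 5); aE <- jit(10L, 292, 300)
      bS <- jit(10L, 301, 305); bE <- jit(10L, 592, 600)
      rowsA <- vapply(1:10, function(i)
        .tabRow(qid, sprintf("hA%02d", i), shuffled[i], bits20[i],
                aS[i], aE[i], aS[i], aE[i], 300L, 0L,
                substr(consA, aS[i], aE[i]),
                substr(famA[i], aS[i], aE[i])), character(1))
      rowsB <- vapply(1:10, function(i)
        .tabRow(qid, sprintf("hB%02d", i), shuffled[10L + i],
                bits20[10L + i],
                bS[i], bE[i], bS[i] - 300L, bE[i] - 300L, 300L, 0L,
                substr(consB, bS[i] - 300L, bE[i] - 300L),
                substr(famB[i], bS[i] - 300L, bE[i] - 300L)), character(1))
      rows <- c(rowsA, rowsB)
      expectation <- c(length_cluster = "fail", length_rank = "fail",
                       duplication = "pass", gene_merge = "fail")
    } else if (kind == "duplicated") {
      # repeat the C-terminal 40% in tandem: positions 121..200 twice
      res <- paste0(cons, substr(cons, 121L, 200L))
      query <- protRec(res)
      rows <- unlist(lapply(seq_along(members), function(i) {
        e2 <- ev[i] * 10^stats::runif(1, 1, 3)   # second HSP less significant
        c(.tabRow(qid, sprintf("h%02d", i), ev[i], bits[i],
                  1L, 280L, 1L, 200L, 200L, 0L,
                  res, paste0(members[i], strrep("-", 80L))),
          .tabRow(qid, sprintf("h%02d", i), e2, bits[i] - 150L,
                  201L, 280L, 121L, 200L, 200L, 0L,
                  substr(res, 201L, 280L), substr(members[i], 121L, 200L)))
      }))
      expectation <- c(length_cluster = "fail", length_rank = "fail",
                       duplication = "fail", conserved_regions = "fail",
                       gene_merge = "pass")
    } else if (kind == "frameshifted") {
      aa <- .splitChars(cons)
      # plant residues whose canonical codons create stop codons at the
      # frame boundaries once a base is inserted after codon 100:
      # L(CTA)|K(AAA) reads TAA in frame +2; T|K(AAA) reads TAA in frame +1
      aa[99L] <- "L"; aa[100L] <- "K"; aa[101L] <- "K"
      aaStr <- paste(aa, collapse = "")
      nt0 <- .backTranslate(aaStr)
      nt <- paste0(substr(nt0, 1L, 300L), "T", substr(nt0, 301L, 600L))
      query <- new("SequenceRecord", id = qid, defline = defl(qid),
                   residues = nt, alphabet = "nucleotide")
      qseq1 <- substr(aaStr, 1L, 100L); qseq2 <- substr(aaStr, 101L, 200L)
      rows <- unlist(lapply(seq_along(members), function(i) {
        e2 <- ev[i] * 10^stats::runif(1, 0, 2)
        c(.tabRow(qid, sprintf("h%02d", i), ev[i], bits[i],
                  1L, 300L, 1L, 100L, 200L, 1L,
                  qseq1, substr(members[i], 1L, 100L)),
          .tabRow(qid, sprintf("h%02d", i), e2, bits[i] - 100L,
                  302L, 601L, 101L, 200L, 200L, 2L,
                  qseq2, substr(members[i], 101L, 200L)))
      }))
      expectation <- c(length_cluster = "pass", length_rank = "pass",
                       duplication = "pass", gene_merge = "fail",
                       orf_ab_initio = "fail", orf_similarity = "fail")
    }

    new("GVScenario", kind = kind, seed = seed, query = query,
        hitsTable = rows, expectation = expectation)
  })
}

#' Parse a scenario's fabricated BLAST table into hits
#'
#' @param scenario a [GVScenario-class].
#' @param maxHits per-query hit cap.
#' @return list of [BlastHit-class] for the scenario's query (empty for
#'   the no_hits kind).
#' @export
scenarioHits <- function(scenario, maxHits = 500L) {
  stopifnot(is(scenario, "GVScenario"))
  if (!length(scenario@hitsTable)) return(list())
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(scenario@hitsTable, tmp)
  parseBlastTabular(tmp, maxHits = maxHits)[[scenario@query@id]]
}

#' Run the validation engine on a scenario
#'
#' @param scenario a [GVScenario-class].
#' @param config a [gvConfig()] list.
#' @return a [QueryReport-class].
#' @export
runScenario <- function(scenario, config = gvConfig()) {
  validateQuery(scenario@query, scenarioHits(scenario, config$maxHits),
                config)
}

#' Write a scenario to disk
#'
#' Writes `query.fasta`, `hits.tsv` and `expectation.json` into a
#' directory, the on-disk form consumed by the command-line interface.
#'
#' @param scenario a [GVScenario-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeScenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c(paste0(">", scenario@query@defline),
               scenario@query@residues),
             file.path(dir, "query.fasta"))
  writeLines(scenario@hitsTable, file.path(dir, "hits.tsv"))
  jsonlite::write_json(as.list(scenario@expectation),
                       file.path(dir, "expectation.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
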