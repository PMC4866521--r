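test_that("FASTA queries are read in order with the right alphabet", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">q1 some description", "MKV", ">q2", "MKVLWAALLV"), f)
  recs <- readQueries(f)
  expect_length(recs, 2L)
  expect_equal(queryId(recs[[1]]), "q1")
  expect_equal(residues(recs[[1]]), "MKV")
  expect_equal(alphabet(recs[[1]]), "protein")
  expect_equal(recs[[1]]@defline, "q1 some description")

  writeLines(c(">q1", "ATGAAA"), f)
  expect_equal(alphabet(readQueries(f)[[1]]), "nucleotide")
})

test_that("FASTA errors are explicit", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1", "MKV", ">g1", "MKL"), f)
  expect_error(readQueries(f), "g1")
  writeLines(character(), f)
  expect_error(readQueries(f), "no sequences")
  writeLines(c("MKV", ">q1", "MKL"), f)
  expect_error(readQueries(f), "line 1")
  writeLines(c(">p", "MKVLW", ">n", "ATGATGATGATG"), f)
  expect_error(readQueries(f), "mixed alphabets")
  expect_length(readQueries(f, alphabet = "protein"), 2L)
})

test_that("alphabet detection uses the 90% nucleotide-character rule", {
  expect_equal(detectAlphabet("ACGTACGT"), "nucleotide")
  expect_equal(detectAlphabet("MKVLW"), "protein")
  # 9 of 10 characters nucleotide-like: exactly at the 0.9 threshold
  expect_equal(detectAlphabet("ACGTACGTAW"), "nucleotide")
  expect_equal(detectAlphabet("ACGTACGWWA"), "protein")
  expect_error(detectAlphabet("MK8V"), "invalid")
})

test_that("MAKER QI deflines parse field by field", {
  qi <- parseMakerQI("g1 AED:0.05 QI:0|0.77|0.68|1|0.77|0.78|5|462|824")
  expect_s3_class(qi, "maker_qi")
  expect_equal(qi$utr5_len, 0)
  expect_equal(qi$splice_est_frac, 0.77)
  expect_equal(qi$exon_est_frac, 0.68)
  expect_equal(qi$exon_evidence_frac, 1)
  expect_equal(qi$n_exons, 5)
  expect_equal(qi$utr3_len, 462)
  expect_equal(qi$protein_len, 824)
  expect_null(parseMakerQI("g1 no tag here"))
  expect_warning(res <- parseMakerQI("g1 QI:0|0.5"), "malformed")
  expect_null(res)
  expect_warning(parseMakerQI("g1 QI:a|b|c|d|e|f|g|h|i"), "malformed")
})

test_that("BLAST coordinates normalize to 0-based half-open", {
  expect_equal(normalizeHspCoords(1, 100, 0, 100), list(qStart = 0, qEnd = 100))
  expect_equal(normalizeHspCoords(300, 1, -1, 300), list(qStart = 0, qEnd = 300))
  expect_error(normalizeHspCoords(0, 10, 0, 10), "1-based")
  expect_error(normalizeHspCoords(1, 101, 0, 100), "exceeds")
})

test_that("tabular parsing groups rows into sorted hits", {
  f <- withr::local_tempfile(fileext = ".tsv")
  minimal <- "qseqid sseqid evalue bitscore qstart qend sstart send slen"
  writeLines("q1\th1\t1e-50\t200\t1\t100\t1\t100\t100", f)
  m <- parseBlastTabular(f, minimal)
  expect_named(m, "q1")
  h <- m$q1[[1]]
  expect_equal(h@id, "h1")
  expect_equal(h@length, 100L)
  expect_equal(hsps(h)$qStart, 0L)
  expect_equal(hsps(h)$qEnd, 100L)
  expect_equal(hsps(h)$hStart, 0L)
  expect_equal(hsps(h)$hEnd, 100L)

  writeLines(character(), f)
  expect_length(parseBlastTabular(f, minimal), 0L)

  writeLines(c("# outfmt 7 comment",
               "q1\th1\t1e-50\t200\t1\t100\t1\t100\t100",
               "q1\th1\t1e-10\t80\t120\t180\t10\t70\t100"), f)
  m <- parseBlastTabular(f, minimal)
  expect_length(m$q1, 1L)
  expect_equal(nrow(hsps(m$q1[[1]])), 2L)
  # HSPs sorted by ascending e-value
  expect_equal(hsps(m$q1[[1]])$evalue, c(1e-50, 1e-10))

  expect_error(parseBlastTabular(f, "qseqid sseqid evalue"), "mandatory")
  writeLines("q1\th1\t1e-50", f)
  expect_error(parseBlastTabular(f, minimal), "line 1")
})

test_that("tabular round trip is exact", {
  for (kind in c("clean", "fused", "duplicated")) {
    sc <- makeScenario(kind, 7)
    f1 <- withr::local_tempfile(fileext = ".tsv")
    f2 <- withr::local_tempfile(fileext = ".tsv")
    writeLines(sc@hitsTable, f1)
    m1 <- parseBlastTabular(f1)
    writeBlastTabular(m1, f2)
    m2 <- parseBlastTabular(f2)
    expect_equal(names(m1), names(m2))
    for (q in names(m1)) {
      expect_equal(length(m1[[q]]), length(m2[[q]]))
      for (i in seq_along(m1[[q]])) {
        expect_equal(m1[[q]][[i]]@id, m2[[q]][[i]]@id)
        expect_identical(hsps(m1[[q]][[i]])$evalueStr,
                         hsps(m2[[q]][[i]])$evalueStr)
        expect_identical(
          hsps(m1[[q]][[i]])[c("qStart", "qEnd", "hStart", "hEnd")],
          hsps(m2[[q]][[i]])[c("qStart", "qEnd", "hStart", "hEnd")])
      }
    }
  }
})

test_that("XML parsing matches tabular parsing on paired fixtures", {
  sc <- makeScenario("clean", 42)
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(sc@hitsTable, tf)
  tab <- parseBlastTabular(tf)$q_clean
  xf <- withr::local_tempfile(fileext = ".xml")
  writeLines(blastXmlDoc("q_clean", nchar(residues(sc@query)), tab), xf)
  xml <- parseBlastXml(xf)$q_clean
  expect_equal(length(xml), length(tab))
  for (i in seq_along(tab)) {
    expect_equal(xml[[i]]@id, tab[[i]]@id)
    expect_equal(xml[[i]]@length, tab[[i]]@length)
    expect_equal(
      hsps(xml[[i]])[c("qStart", "qEnd", "hStart", "hEnd", "qFrame")],
      hsps(tab[[i]])[c("qStart", "qEnd", "hStart", "hEnd", "qFrame")])
    expect_equal(hsps(xml[[i]])$evalue, hsps(tab[[i]])$evalue)
  }
})

test_that("blastx XML minus-frame coordinates are stored ascending", {
  hit <- testHit("h1", 100L,
                 hspRow(0L, 300L, 0L, 100L, qFrame = -2L))
  xf <- withr::local_tempfile(fileext = ".xml")
  writeLines(blastXmlDoc("q1", 300L, list(hit), program = "blastx"), xf)
  m <- parseBlastXml(xf)
  h <- hsps(m$q1[[1]])
  expect_equal(h$qFrame, -2L)
  expect_lt(h$qStart, h$qEnd)
  expect_equal(c(h$qStart, h$qEnd), c(0L, 300L))
})

test_that("XML with no hits yields an empty hit list, bad program errors", {
  xf <- withr::local_tempfile(fileext = ".xml")
  writeLines(blastXmlDoc("q1", 100L, list()), xf)
  m <- parseBlastXml(xf)
  expect_named(m, "q1")
  expect_length(m$q1, 0L)
  writeLines(blastXmlDoc("q1", 100L, list(), program = "blastn"), xf)
  expect_error(parseBlastXml(xf), "blastn")
})

test_that("no parsed HSP ever has qStart >= qEnd", {
  for (kind in c("clean", "truncated", "too_long", "fused", "duplicated",
                 "frameshifted")) {
    for (seed in c(7, 42)) {
      hits <- scenarioHits(makeScenario(kind, seed))
      for (h in hits) expect_true(all(hsps(h)$qStart < hsps(h)$qEnd))
    }
  }
})

test_that("hit sequences come from the hit FASTA or ungapped HSP strings", {
  hit <- testHit("h1", 10L, hspRow(0L, 10L, 0L, 10L,
                                   qAln = "MKVLW-ACDEF", hAln = "MKVLWQACD-F"))
  expect_equal(unname(hitSequences(list(hit))), "MKVLWQACDF")
  expect_equal(unname(hitSequences(list(hit),
                                   hitFasta = c(h1 = "MKVLWQACDEF"))),
               "MKVLWQACDEF")
  noAln <- testHit("h2", 10L, hspRow(0L, 10L, 0L, 10L))
  expect_true(is.na(hitSequences(list(noAln))))
})
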