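reportsForTest <- function() {
  list(runScenario(makeScenario("clean", 42)),
       runScenario(makeScenario("fused", 7)),
       runScenario(makeScenario("no_hits", 7)),
       runScenario(makeScenario("frameshifted", 42)))
}

test_that("JSON reports round-trip losslessly", {
  reps <- reportsForTest()
  f <- withr::local_tempfile(fileext = ".json")
  renderJson(reps, f, timestamp = "frozen")
  back <- readReportJson(f)
  expect_equal(back$metadata$tool, "genecheck")
  expect_length(back$reports, length(reps))
  for (i in seq_along(reps)) {
    a <- reps[[i]]; b <- back$reports[[i]]
    expect_equal(queryId(b), queryId(a))
    expect_equal(b@nHits, a@nHits)
    expect_equal(score(b), score(a))
    expect_identical(verdictStatuses(b), verdictStatuses(a))
    for (k in seq_along(verdicts(a))) {
      va <- verdicts(a)[[k]]; vb <- verdicts(b)[[k]]
      expect_equal(statistic(vb), statistic(va))
      expect_equal(vb@threshold, va@threshold)
      expect_equal(pValue(vb), pValue(va))
      expect_equal(vb@message, va@message)
      if (!is.null(plotPayload(va)))
        expect_equal(plotPayload(vb)@series, lapply(plotPayload(va)@series,
                                                    as.numeric))
    }
  }
})

test_that("an empty report list still renders a valid JSON document", {
  f <- withr::local_tempfile(fileext = ".json")
  renderJson(list(), f, timestamp = "frozen")
  doc <- jsonlite::read_json(f)
  expect_equal(doc$schema_version, "1.0")
  expect_length(doc$queries, 0L)
})

test_that("the documented JSON path carries the combined score", {
  reps <- list(runScenario(makeScenario("truncated", 7)))
  f <- withr::local_tempfile(fileext = ".json")
  renderJson(reps, f, timestamp = "frozen")
  doc <- jsonlite::read_json(f)
  expect_equal(doc$queries[[1]]$score, score(reps[[1]]))
})

test_that("TSV reports have the documented layout", {
  f <- withr::local_tempfile(fileext = ".tsv")
  renderTsv(list(), f)
  lines <- readLines(f)
  expect_length(lines, 1L)
  expect_equal(strsplit(lines, "\t")[[1]][1:3], c("query_id", "score", "n_hits"))

  reps <- list(runScenario(makeScenario("clean", 42)),
               runScenario(makeScenario("no_hits", 7)))
  renderTsv(reps, f)
  tab <- readReportTsv(f)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$query_id, c("q_clean", "q_no_hits"))
  expect_equal(tab$score[1], "100")
  # five decided passes + two skipped ORF columns for a clean protein query
  expect_equal(unname(unlist(tab[1, c("length_cluster", "length_rank",
                                      "duplication", "conserved_regions",
                                      "gene_merge")])), rep("pass", 5))
  expect_equal(tab$maker_qi[1], "")
  # no hits: empty score, BLAST-dependent analyses skipped
  expect_equal(tab$score[2], "")
  expect_equal(tab$length_cluster[2], "skipped")
  expect_false(any(grepl("\r", readLines(f, warn = FALSE))))
})

test_that("JSON and TSV state identical scores and statuses", {
  reps <- reportsForTest()
  fj <- withr::local_tempfile(fileext = ".json")
  ft <- withr::local_tempfile(fileext = ".tsv")
  renderJson(reps, fj, timestamp = "frozen")
  renderTsv(reps, ft)
  back <- readReportJson(fj)$reports
  tab <- readReportTsv(ft)
  for (i in seq_along(reps)) {
    expect_equal(tab$query_id[i], queryId(back[[i]]))
    jscore <- if (is.na(score(back[[i]]))) "" else as.character(score(back[[i]]))
    expect_equal(tab$score[i], jscore)
    st <- verdictStatuses(back[[i]])
    for (nm in names(st)) expect_equal(tab[[nm]][i], unname(st[nm]))
  }
})

test_that("HTML reports are well-formed with bounded, finite graph panels", {
  reps <- reportsForTest()
  f <- withr::local_tempfile(fileext = ".html")
  renderHtml(reps, f, timestamp = "frozen")
  doc <- xml2::read_html(f)      # parse failure would error
  sections <- xml2::xml_find_all(doc, "//section")
  expect_length(sections, length(reps))
  for (i in seq_along(reps)) {
    svgs <- xml2::xml_find_all(sections[[i]], ".//svg")
    expect_lte(length(svgs), 5L)
  }
  # nucleotide query with hits: all five graph kinds
  ntSection <- sections[[4]]
  expect_length(xml2::xml_find_all(ntSection, ".//svg"), 5L)
  # protein query with hits: four (no ORF tracks)
  expect_length(xml2::xml_find_all(sections[[1]], ".//svg"), 4L)
  # no-hits section explains itself
  expect_match(xml2::xml_text(sections[[3]]), "no hits; analyses skipped")
  # every numeric SVG coordinate is finite
  html <- paste(readLines(f, warn = FALSE), collapse = "\n")
  expect_false(grepl("NaN|Inf", html))
})

test_that("end-to-end runs write reproducible reports", {
  dir <- withr::local_tempdir()
  writeScenario(makeScenario("clean", 42), dir)
  out1 <- file.path(dir, "out1"); out2 <- file.path(dir, "out2")
  res <- runValidation(file.path(dir, "query.fasta"),
                       file.path(dir, "hits.tsv"),
                       outputDir = out1, timestamp = "frozen", quiet = TRUE)
  expect_length(res$files, 3L)
  tab <- readReportTsv(file.path(out1, "report.tsv"))
  expect_equal(tab$score, "100")
  runValidation(file.path(dir, "query.fasta"), file.path(dir, "hits.tsv"),
                outputDir = out2, timestamp = "frozen", quiet = TRUE)
  for (nm in c("report.json", "report.tsv", "report.html"))
    expect_identical(readBin(file.path(out1, nm), "raw", 1e7),
                     readBin(file.path(out2, nm), "raw", 1e7))
  expect_error(runValidation(file.path(dir, "absent.fasta"),
                             file.path(dir, "hits.tsv"),
                             outputDir = out1, quiet = TRUE), "cannot read")
})

test_that("queries in the FASTA but not in the BLAST output are skipped, not dropped", {
  dir <- withr::local_tempdir()
  writeScenario(makeScenario("clean", 42), dir)
  fasta <- file.path(dir, "query.fasta")
  extra <- c(readLines(fasta), ">q_orphan", strrep("MKVLW", 30))
  writeLines(extra, fasta)
  res <- runValidation(fasta, file.path(dir, "hits.tsv"),
                       outputDir = file.path(dir, "out"),
                       timestamp = "frozen", quiet = TRUE)
  expect_length(res$reports, 2L)
  st <- verdictStatuses(res$reports[[2]])
  expect_true(all(st[c("length_cluster", "length_rank", "duplication",
                       "conserved_regions", "gene_merge")] == "skipped"))
  expect_true(is.na(score(res$reports[[2]])))
})
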