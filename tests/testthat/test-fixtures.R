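test_that("families are deterministic and respect divergence zero", {
  expect_equal(makeFamily(1, 50, 4, 0), rep(makeFamily(1, 50, 4, 0)[1], 4))
  expect_identical(makeFamily(1, 100, 5, 0.1), makeFamily(1, 100, 5, 0.1))
  expect_false(identical(makeFamily(1, 100, 5, 0.1),
                         makeFamily(2, 100, 5, 0.1)))
  expect_error(makeFamily(1, 50, 1, 0.1))
  expect_error(makeFamily(1, 50, 4, 0.5))
})

test_that("pairwise identity matches the substitution-model expectation", {
  # site equality between two members: a^2 + 19 (d/20)^2, a = 1 - 19d/20
  d <- 0.1
  a <- 1 - d + d / 20
  expected <- a^2 + 19 * (d / 20)^2
  L <- 100L
  ident <- vapply(1:50, function(s) {
    fam <- makeFamily(1000 + s, L, 2, d)
    mean(strsplit(fam[1], "")[[1]] == strsplit(fam[2], "")[[1]])
  }, numeric(1))
  se <- sqrt(expected * (1 - expected) / (L * 50))
  expect_lt(abs(mean(ident) - expected), 3 * se)
})

test_that("scenario regeneration is identical and leaves the RNG untouched", {
  s1 <- makeScenario("fused", 42)
  set.seed(99)
  before <- .Random.seed
  s2 <- makeScenario("fused", 42)
  expect_identical(before, .Random.seed)
  expect_identical(s1@query@residues, s2@query@residues)
  expect_identical(s1@hitsTable, s2@hitsTable)
  expect_error(makeScenario("bogus", 1))
})

test_that("fabricated tables parse cleanly into valid hits", {
  for (kind in c("clean", "truncated", "too_long", "fused", "duplicated",
                 "frameshifted", "no_hits")) {
    sc <- makeScenario(kind, 1337)
    expect_warning(hits <- scenarioHits(sc), regexp = NA)
    if (kind == "no_hits") {
      expect_length(hits, 0L)
    } else {
      expect_gte(length(hits), 10L)
      for (h in hits) expect_true(validObject(h))
      ev <- vapply(hits, bestEvalue, numeric(1))
      expect_true(all(diff(ev) >= 0))
    }
  }
})

test_that("scenarios can be written to disk and consumed end-to-end", {
  dir <- withr::local_tempdir()
  sc <- makeScenario("duplicated", 7)
  writeScenario(sc, dir)
  expect_true(all(file.exists(file.path(dir, c("query.fasta", "hits.tsv",
                                               "expectation.json")))))
  exp <- jsonlite::read_json(file.path(dir, "expectation.json"),
                             simplifyVector = TRUE)
  expect_equal(exp$duplication, "fail")
  res <- runValidation(file.path(dir, "query.fasta"),
                       file.path(dir, "hits.tsv"),
                       outputDir = file.path(dir, "out"),
                       timestamp = "frozen", quiet = TRUE)
  st <- verdictStatuses(res$reports[[1]])
  expect_equal(unname(st["duplication"]), "fail")
})
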