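test_that("length clustering accepts queries inside the main cluster", {
  hits <- hitsOfLengths(c(rep(100L, 9), 500L), qlen = 90L)
  q <- protRecord(strrep("M", 102))
  v <- validateLengthCluster(q, hits)
  expect_equal(verdictStatus(v), "pass")
  expect_equal(statistic(v), 102)
  expect_equal(v@threshold, c(90, 110))

  v2 <- validateLengthCluster(protRecord(strrep("M", 480)), hits)
  expect_equal(verdictStatus(v2), "fail")

  v3 <- validateLengthCluster(q, hits[1:3])
  expect_equal(verdictStatus(v3), "skipped")
  expect_match(v3@message, "too few")
})

test_that("length rank flags extreme ranks with direction", {
  lens <- c(80L, 85L, 90L, 95L, 98L, 100L, 102L, 105L, 110L, 115L, 120L)
  hits <- hitsOfLengths(lens, qlen = 70L)
  v <- validateLengthRank(protRecord(strrep("M", 100)), hits)
  expect_equal(verdictStatus(v), "pass")
  expect_equal(statistic(v), 0.5)

  short <- validateLengthRank(protRecord(strrep("M", 50)), hits[1:10])
  expect_equal(verdictStatus(short), "fail")
  expect_equal(statistic(short), 0)
  expect_match(short@message, "too short")

  long <- validateLengthRank(protRecord(strrep("M", 112)),
                             hitsOfLengths(lens[1:10], qlen = 70L))
  expect_equal(verdictStatus(long), "fail")
  expect_equal(statistic(long), 0.9)
  expect_match(long@message, "too long")
})

test_that("duplication passes on single coverage and fails on doubled regions", {
  q <- protRecord(strrep("M", 120))
  adjacent <- testHit("h1", 100L,
                      rbind(hspRow(0, 50, 0, 50, evalue = 1e-60),
                            hspRow(50, 100, 50, 100, evalue = 1e-50)))
  v <- validateDuplication(q, list(adjacent))
  expect_equal(verdictStatus(v), "pass")

  doubled <- testHit("h1", 100L,
                     rbind(hspRow(0, 80, 0, 80, evalue = 1e-60),
                           hspRow(40, 120, 0, 80, evalue = 1e-50)))
  v2 <- validateDuplication(q, list(doubled))
  expect_equal(verdictStatus(v2), "fail")
  expect_lt(pValue(v2), 0.05)
  expect_equal(statistic(v2), 2)           # every covered position hit twice

  expect_equal(verdictStatus(validateDuplication(q, list())), "skipped")
})

test_that("conserved regions pass on a faithful query and fail on a deletion", {
  base <- makeFamily(41, 100, 2, 0)[1]
  hits <- lapply(1:10, function(i)
    testHit(sprintf("h%02d", i), 100L,
            hspRow(0, 100, 0, 100, evalue = 10^(-80 + i),
                   qAln = base, hAln = base)))
  ok <- validateConservedRegions(protRecord(base), hits)
  expect_equal(verdictStatus(ok), "pass")
  expect_equal(statistic(ok), 0)

  gapped <- paste0(substr(base, 1, 35), substr(base, 66, 100))
  bad <- validateConservedRegions(protRecord(gapped), hits)
  expect_equal(verdictStatus(bad), "fail")
  expect_equal(statistic(bad), 0.30, tolerance = 1e-9)

  expect_equal(verdictStatus(validateConservedRegions(protRecord(base),
                                                      hits[1])), "skipped")
})

test_that("gene merge passes unimodal geometries and flags fusion slopes", {
  q <- protRecord(strrep("M", 350))
  oneRegion <- lapply(1:5, function(i)
    testHit(sprintf("h%d", i), 310L,
            hspRow(0 + i, 300 + i, 0, 300, evalue = 10^(-60 + i))))
  v <- validateGeneMerge(q, oneRegion)
  expect_equal(verdictStatus(v), "pass")
  expect_match(v@message, "unimodal")

  fused <- runScenario(makeScenario("fused", 42))
  gm <- verdictStatuses(fused)["gene_merge"]
  expect_equal(unname(gm), "fail")

  # bimodal coordinates but slope 1.5: outside the merge window
  steep <- lapply(1:8, function(i) {
    x <- if (i <= 4) 2 * (i - 1) else 800 + 2 * (i - 5)
    testHit(sprintf("h%d", i), 1300L,
            hspRow(x, 1.5 * x + 20, 0, 0.5 * x + 20, evalue = 1e-50))
  })
  v3 <- validateGeneMerge(protRecord(strrep("M", 1300)), steep)
  expect_equal(verdictStatus(v3), "pass")
  expect_equal(statistic(v3), 1.5, tolerance = 1e-9)

  expect_equal(verdictStatus(validateGeneMerge(q, oneRegion[1:3])), "skipped")
})

test_that("fusion detection is monotone in the second gene's hit support", {
  sc <- makeScenario("fused", 42)
  base <- scenarioHits(sc)
  extraB <- base[grepl("^hB", vapply(base, function(h) h@id, character(1)))]
  hits <- base
  for (k in 1:3) {
    more <- lapply(extraB, function(h) {
      h@id <- paste0(h@id, "_x", k)
      h@hsps$evalue <- h@hsps$evalue * 10^-k
      h@hsps$evalueStr <- sprintf("%.3e", h@hsps$evalue)
      h
    })
    hits <- c(hits, more)
    v <- validateGeneMerge(sc@query, hits)
    expect_equal(verdictStatus(v), "fail")
  }
})

test_that("ab initio ORF analysis wants exactly one major ORF", {
  clean <- makeScenario("clean", 42, alphabet = "nucleotide")
  v <- validateOrfAbInitio(clean@query)
  expect_equal(verdictStatus(v), "pass")
  expect_equal(statistic(v), 1)

  shifted <- makeScenario("frameshifted", 42)
  v2 <- validateOrfAbInitio(shifted@query)
  expect_equal(verdictStatus(v2), "fail")
  expect_gte(statistic(v2), 2)

  noOrf <- ntRecord(strrep("TAATTAC", 30))
  v3 <- validateOrfAbInitio(noOrf)
  expect_equal(verdictStatus(v3), "fail")
  expect_match(v3@message, "no ORF")

  expect_equal(verdictStatus(validateOrfAbInitio(protRecord("MKV"))),
               "skipped")
})

test_that("similarity ORF analysis measures hit concentration in one frame", {
  clean <- makeScenario("clean", 42, alphabet = "nucleotide")
  v <- validateOrfSimilarity(clean@query, scenarioHits(clean))
  expect_equal(verdictStatus(v), "pass")
  expect_equal(statistic(v), 1)

  shifted <- makeScenario("frameshifted", 42)
  v2 <- validateOrfSimilarity(shifted@query, scenarioHits(shifted))
  expect_equal(verdictStatus(v2), "fail")
  expect_equal(statistic(v2), 302 / 600, tolerance = 1e-9)

  expect_equal(verdictStatus(validateOrfSimilarity(clean@query, list())),
               "skipped")
})

test_that("MAKER QI verdicts average the EST support fields", {
  q <- protRecord("MKV", defline = "q1 QI:0|1.0|1.0|1|0.5|0.5|4|0|3")
  v <- validateMakerQI(q)
  expect_equal(verdictStatus(v), "pass")
  expect_equal(statistic(v), 1)

  q2 <- protRecord("MKV", defline = "q1 QI:0|0.77|0.68|1|0.5|0.5|4|0|3")
  v2 <- validateMakerQI(q2)
  expect_equal(verdictStatus(v2), "fail")
  expect_equal(statistic(v2), 0.725)

  expect_equal(verdictStatus(validateMakerQI(protRecord("MKV"))), "skipped")
  q3 <- protRecord("MKV", defline = "q1 QI:0|-1|-1|1|0.5|0.5|4|0|3")
  expect_equal(verdictStatus(validateMakerQI(q3)), "skipped")
  # one available field: use it alone
  q4 <- protRecord("MKV", defline = "q1 QI:0|-1|0.9|1|0.5|0.5|4|0|3")
  expect_equal(statistic(validateMakerQI(q4)), 0.9)
})

test_that("verdicts are deterministic across repeated runs", {
  for (kind in c("clean", "fused", "frameshifted")) {
    r1 <- runScenario(makeScenario(kind, 7))
    r2 <- runScenario(makeScenario(kind, 7))
    expect_identical(verdictStatuses(r1), verdictStatuses(r2))
    expect_identical(vapply(verdicts(r1), statistic, numeric(1)),
                     vapply(verdicts(r2), statistic, numeric(1)))
    expect_identical(score(r1), score(r2))
  }
})

test_that("a nucleotide query with hits runs seven analyses, eight with QI", {
  plain <- makeScenario("clean", 42, alphabet = "nucleotide")
  rep1 <- runScenario(plain)
  expect_length(verdicts(rep1), 7L)
  expect_false("maker_qi" %in% names(verdictStatuses(rep1)))

  tagged <- makeScenario("clean", 42, alphabet = "nucleotide", withQI = TRUE)
  rep2 <- runScenario(tagged)
  expect_length(verdicts(rep2), 8L)
  expect_equal(unname(verdictStatuses(rep2)["maker_qi"]), "pass")
})
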