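Package: genecheck
Title: Quality Validation of Protein-Coding Gene Predictions from BLAST Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates protein-coding gene predictions against pre-computed
    BLAST results. For each query up to seven analyses compare the prediction
    with its most significant database hits: length clustering and a length
    rank test, a Wilcoxon coverage test for internal duplication, alignment
    to a position-specific scoring profile of the top hits to find missing or
    extra regions, weighted HSP start-stop regression to detect merged genes,
    and two open-reading-frame checks for nucleotide queries, plus an
    optional MAKER quality-index check. Verdicts are combined into a 0-100
    score per gene and written as JSON, TSV and self-contained HTML reports
    with inline SVG diagnostics. A deterministic scenario generator fabricates
    query/BLAST pairs with planted defects for hermetic testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    xml2,
    Biostrings,
    IRanges,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
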