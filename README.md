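# genecheck

Quality control for protein-coding gene predictions.  Even good gene
predictors truncate models, retain intronic sequence, fragment genes and
merge neighbours; genecheck flags such problems automatically by comparing
each predicted gene with its most significant BLAST hits from a reference
protein database, so curators can rank thousands of models and spend their
time on the broken ones.

For each query (protein or nucleotide FASTA, paired with pre-computed
blastp/blastx output) up to seven analyses each return a binary verdict:

| analysis | question | decision rule |
|---|---|---|
| `length_cluster` | is the query length typical of its hits? | query length inside the densest single-linkage cluster of hit lengths, ±10 % |
| `length_rank` | is its length rank extreme? | fractional rank *r*; fail if *r* < 0.2 (too short) or *r* > 0.8 (too long) |
| `duplication` | are hit regions matched more than once? | one-sample Wilcoxon signed-rank test of pooled hit coverage vs 1; fail if *p* < 0.05 |
| `conserved_regions` | are conserved regions missing or extra? | query vs PSSM profile of the top 10 hits; fail if missing+extra > 20 % of core columns |
| `gene_merge` | does the model fuse two genes? | bimodal HSP coordinates and weighted start–stop regression slope in [0.4, 1.2] |
| `orf_ab_initio` | one major ORF? (nucleotide only) | fail unless exactly one ORF ≥ 0.8 × the longest |
| `orf_similarity` | do hits sit in one ORF? (nucleotide only) | fail if < 80 % of HSP-covered nt fall in a single ORF |
| `maker_qi` | is there RNA-seq support? (MAKER deflines) | mean EST-support fraction ≥ 0.8 |

Decided verdicts combine into a score
`round(100 · #pass / (#pass + #fail))`; skipped analyses are neutral.
Reports are written as JSON, TSV and a self-contained HTML file with up to
five inline-SVG graphs per gene.

## Worked example

The package ships a deterministic scenario generator that fabricates
(query, BLAST tabular) pairs with planted defects — here a query fusing
two unrelated genes:

```r
library(genecheck)
sc <- makeScenario("fused", 42)
report <- runScenario(sc)
show(report)
#> QueryReport q_fused: 20 hit(s), score 20
#> [fail] length_cluster  statistic=600  query length 600 aa lies outside the main hit-length cluster interval [270.0, 330.0]
#> [fail] length_rank  statistic=1  length rank 1.00: query looks too long
#> [pass] duplication  statistic=1  no multi-HSP hit; nothing matched twice
#> [fail] conserved_regions  statistic=0.9649  330 of 342 core profile columns missing or extra (fraction 0.96): query deviates from the hit profile
#> [fail] gene_merge  statistic=1.013  bimodal HSP coordinates; weighted start-stop regression slope 1.01 inside the merge window [0.4, 1.2]
#> [skipped] orf_ab_initio  statistic=NA  protein query: no reading frames
#> [skipped] orf_similarity  statistic=NA  protein query: no reading frames
```

The 600-aa fusion is twice as long as its 300-aa hits (both length tests
fail), matches each hit family over only half its length (conserved
regions fail), and its HSP start/stop coordinates are bimodal with a
regression slope of 1.01 — inside the empirical [0.4, 1.2] merge window —
so `gene_merge` fails: one passed analysis out of five decided gives
score 20.

On real data, run end-to-end from files and write all three report
formats:

```r
runValidation("queries.fasta", "hits.tsv",
              blastFormat = "tabular", outputDir = "reports",
              formats = c("json", "tsv", "html"))
```

or from a shell via the bundled wrapper:

```sh
Rscript inst/scripts/genecheck.R validate -i queries.fasta -b hits.tsv -o reports
Rscript inst/scripts/genecheck.R fixtures --kind fused --seed 42 --out demo/
```

BLAST tabular input defaults to the column string
`qseqid sseqid evalue bitscore qstart qend sstart send slen qframe qseq sseq`
(override with `columns=`); NCBI BLAST XML is parsed with
`blastFormat = "xml"`.  Thresholds live in `gvConfig()` and can be loaded
from a `key=value` file.

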