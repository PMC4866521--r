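---
title: "Validating gene predictions against BLAST evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating gene predictions against BLAST evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genecheck)
```

## The problem

Automated gene predictors make characteristic mistakes: models truncated at
a lost exon, non-coding sequence retained inside an exon, one real gene
fragmented into several models, or two neighbouring genes merged into one.
Manually spotting these defects takes minutes to days per gene.  genecheck
automates the triage: each predicted gene is compared with its most
significant BLAST hits from a reference protein database, and every
comparison returns a binary verdict (consistent or inconsistent with the
hits) from a p-value or an empirical cutoff.  The verdicts are combined
into a 0–100 score used to rank genes, or whole gene sets, for curation.

genecheck never runs BLAST itself: the user supplies pre-computed blastp
(protein queries) or blastx (nucleotide queries) output in tabular
(outfmt 6/7, with a declared column string) or XML form.  All coordinates
are normalised once, at the parse boundary, to 0-based half-open intervals
ascending on the plus strand; every analysis downstream sees only this one
convention, which removes a whole class of off-by-one errors across seven
analyses.

## The analyses

Four analyses run on every query with hits:

**Length (clustering).**  Hit lengths are clustered by single-linkage
agglomeration in one dimension.  Merging stops when the smallest
inter-cluster gap exceeds `max(5, 0.1 × median hit length)` amino acids;
the densest cluster, widened by a relative tolerance of 0.1, defines the
accepted interval for the query length (nucleotide query lengths are
converted as `floor(len/3)`).  The gap rule and tolerance are empirical
choices of this implementation: single-linkage in 1-D reduces to cutting
sorted lengths at large gaps, which is deterministic and scale-aware.

**Length (rank).**  The fractional rank `r` of the query length among the
hit lengths (ties count one half) flags the query as too short when
`r < 0.2` and too long when `r > 0.8`.  The 0.2/0.8 cutoffs mirror the
"particularly low or high rank" idea as a symmetric empirical rule;
both cutoffs are configurable.  Both length analyses require at least five
hits, otherwise they skip.

**Duplication (coverage).**  For each of the top ten hits, per-position
coverage counts over the *hit's* residues are accumulated from that hit's
HSP hit-side intervals.  Covered positions are pooled across hits and a
one-sample Wilcoxon signed-rank test of median coverage = 1 against > 1 is
applied (zero differences dropped, midranks for ties).  For up to 25
non-zero differences the p-value is exact — the null distribution of the
positive-rank sum is built by subset-sum convolution over the doubled
midranks, so ties are handled exactly; beyond that a normal approximation
with tie correction and a 0.5 continuity correction is used.  Coverage is
pooled across hits rather than tested per hit because a merged tandem
duplicate doubles coverage on *every* informative hit, and pooling gives
the test power when individual hits have few covered positions; per-hit
counts remain visible in the hit-overview graph.

**Conserved regions (profile).**  The ten most significant hits with
recoverable sequences are multiply aligned and summarised as a
position-specific scoring profile (per-column residue + gap frequencies
with an add-one pseudocount over the 20 amino acids; columns with > 50 %
gaps are non-core).  The built-in aligner is progressive: BLOSUM62 global
pairwise alignments (gap open 11, extend 1) define distances
1 − fractional identity, the centroid sequence seeds the alignment, and
the remaining sequences are inserted in order of increasing distance,
each aligned against the growing alignment's frequency profile.  The query
— or, for nucleotide queries, the translation of the longest ORF — is then
globally aligned to the profile with log₂-odds column scores against a
uniform 1/20 background.  Runs of ≥ 5 core columns deleted from the query
are *missing* regions; runs of ≥ 5 query residues aligned to gap or
non-core columns are *extra* regions.  The verdict fails when missing plus
extra columns exceed 20 % of the core profile length.  The run length of 5
suppresses isolated alignment wobble; the 0.2 fraction is an empirical
cutoff in the same spirit as the others.  With tabular input the hit
sequence is recovered from the ungapped `sseq` of the hit's best HSP, so
only the matched hit region is visible; a hit FASTA can be supplied when
full-length hit sequences are wanted.

**Gene merge (regression).**  HSP start and stop coordinates pooled over
the top ten hits are first checked for unimodality with a deterministic
largest-gap two-split: the sample is bimodal when the gap between the two
cluster means exceeds twice the larger within-cluster standard deviation
(floored at one query unit) and both sides hold at least two points.  A
dip-style test would need a reference distribution; the largest-gap rule
is dependency-free and adequate for the coarse two-block geometry a fusion
produces, and it is deliberately isolated behind `unimodalityCheck()` so it
can be swapped.  If both starts and stops are unimodal the query passes.
Otherwise HSP stop is regressed on HSP start with weights
`−log10(evalue + 1e−250)` (the floor avoids infinite weight at reported
e-value 0), and a slope inside the empirical window [0.4, 1.2] flags the
model as a fusion of two genes.

Two analyses run only on nucleotide queries:

**Ab initio ORF.**  ORFs are maximal stop-free codon runs in the six
frames, reported on plus-strand coordinates; sequence ends act as
boundaries and no start codon is required, since a prediction may
legitimately begin mid-ORF.  Runs shorter than 90 nt (30 codons) are
noise and discarded.  An ORF is *major* when at least 0.8 of the longest
ORF's length; a clean prediction has exactly one major ORF, while
frameshifts, retained introns and merges produce several.

**Similarity ORFs.**  All hits are expected to align within one ORF: the
statistic is the largest fraction of the HSP-covered nucleotides (the
union of HSP query intervals) falling inside a single ORF, and the verdict
fails below 0.8.  Using the union in both numerator and denominator keeps
the statistic in [0, 1] even when HSPs overlap.  This test catches
frameshifts that the ab initio test misses when the spurious ORF is short.

**MAKER quality index.**  MAKER deflines carry a nine-field `QI:` tag.
The verdict averages the two EST-support fields (fractions of splice sites
and of exons confirmed by EST alignment), skipping fields encoded −1, and
passes at mean ≥ 0.8.  Which of the nine fields to consume was an open
choice; the EST pair is used because it directly measures transcript
support, which is what the analysis is meant to capture.  A malformed tag
degrades to a warning, not an error, because the analysis is explicitly
conditional on the tag being available.

## Scoring and reports

Decided verdicts (pass or fail) are combined as
`score = round(100 × passes / (passes + fails))`, rounded half-up.
Skipped and errored analyses are neutral, so protein queries (at most five
decided analyses) and nucleotide queries (up to seven, eight with a QI
tag) remain comparable; equal weighting is used because no principled
weights are available, and the weights live in one place should that
change.  A query with no decided verdict has no score.

Reports are written as JSON (versioned schema, full verdict detail and
plot payloads, stable key order), TSV (one status column per analysis),
and a single self-contained HTML file.  The HTML graphs are inline SVG
generated directly by the package — no JavaScript, no network fetches — so
a report opened years later on an offline machine still renders: a
hit-length histogram with the query marked, HSP start/stop offsets, a
hit-region overview, the conserved-region map, and (for nucleotide
queries) six-frame ORF tracks, at most five panels per gene.

## The scenario generator

Testing against live BLAST output would make every result depend on a
database snapshot.  Instead `makeScenario()` fabricates internally
consistent (query FASTA, BLAST tabular) pairs: the validations consume
only HSP geometry and significance, so fabricated tables exercise them
fully.  A 10-member protein family (200 aa, per-site substitution rate
0.1 — roughly the divergence of confident homologs — with e-values
log-uniform on [1e−100, 1e−20]) yields a `clean` query as the family
consensus; defects are planted on top:

* `truncated` — C-terminal half removed, HSPs clipped;
* `too_long` — 80 % random extension;
* `fused` — two unrelated 300-aa families concatenated, ten HSPs per
  half, giving bimodal coordinates and a regression slope near 1;
* `duplicated` — the C-terminal 40 % repeated in tandem, with a second
  HSP per hit remapping the extra copy onto the same hit region;
* `frameshifted` — a stop-free back-translation with one base inserted at
  the midpoint; the codons flanking the insertion are chosen so stop
  codons appear at the frame boundary (an L·K codon pair reads TAA once
  shifted), deterministically splitting the query into two reading
  frames;
* `no_hits` — an empty table.

Each scenario carries the verdict statuses its construction pins down,
and the test suite asserts them over seeds {7, 42, 1337}.  Scenarios are
regenerated per seed with R's Mersenne-Twister generator inside a scope
that restores the caller's RNG state, which keeps them byte-identical
across platforms without a hand-rolled generator.

What the generator deliberately does not emulate: insertions/deletions in
family evolution (members stay equal-length, so profile alignments of
clean families are gapless), realistic e-value statistics, compositional
bias, and partially overlapping HSP tilings.  Passing the scenario suite
therefore shows the analyses react correctly to the planted geometries; it
does not certify behaviour on the messier alignments of real databases,
where the configurable cutoffs matter.

## Numerical and degenerate-input choices

* Exact Wilcoxon enumeration switches to the normal approximation above
  25 non-zero differences; with all differences zero the p-value is
  undefined and the query passes with no p-value recorded.
* The regression is skipped below four HSPs; with all starts equal the
  fit is degenerate and the query passes with an explanatory message.
* Alphabet auto-detection calls a sequence nucleotide when ≥ 90 % of its
  non-gap characters are A/C/G/T/U/N, requires one alphabet per file, and
  can be overridden.
* Ambiguity codes are canonicalised for scoring (J→L, U→C, O→K; X spreads
  uniformly over the 20 residues) so profiles always normalise to 1.
* Alignment tie-breaks are fixed (match preferred over gap-close on equal
  score), making every verdict deterministic; no analysis draws random
  numbers.
* Hits are capped at 500 per query at parse time and at the configured
  `topHits` (default 10) per analysis, following the "most significant
  hits" logic.

Problem sizes in the shipped tests — 10–20 hits of 100–600 aa per
scenario, three seeds per kind — were chosen as the smallest sizes at
which every analysis is exercised through its decision logic, including
the profile alignment at its full ten-sequence width.

## Limitations

Verdicts are indicative, not ground truth: they inherit the quality of the
reference database, assume homologs share length and structure, and rest
on empirical cutoffs.  A query whose few hits are themselves dubious can
score poorly for reasons unrelated to the prediction.  The built-in
progressive aligner is adequate for ten sequences; an external aligner can
be substituted upstream by passing pre-aligned hit sequences.  Running
BLAST, remote or local, is out of scope by design — the engine consumes
existing BLAST output only.
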