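.newVerdict <- function(name, status, statistic = NA_real_,
                        threshold = NA_real_, pValue = NA_real_,
                        message = "", plot = NULL) {
  new("ValidationVerdict", name = name, status = status,
      statistic = as.numeric(statistic), threshold = as.numeric(threshold),
      pValue = as.numeric(pValue), message = message, plot = plot)
}

.skip <- function(name, why) .newVerdict(name, "skipped", message = why)

.topHits <- function(hits, n) hits[seq_len(min(length(hits), n))]

.queryLenAA <- function(query) {
  if (query@alphabet == "protein") nchar(query@residues)
  else nchar(query@residues) %/% 3L
}

# pooled HSP table (query coordinates) across a list of hits
.pooledHsps <- function(hits) {
  do.call(rbind, lapply(hits, function(h)
    h@hsps[, c("qStart", "qEnd", "qFrame", "evalue")]))
}

#' Length validation by clustering of hit lengths
#'
#' Hit lengths are clustered by single-linkage agglomeration in one
#' dimension (merging stops when the smallest inter-cluster gap exceeds
#' max(5, 0.1 x median hit length) aa); the densest cluster, widened by a
#' relative tolerance, defines the accepted query length interval.
#' Nucleotide query lengths are converted to aa as floor(len/3).
#'
#' @param query a [SequenceRecord-class].
#' @param hits list of [BlastHit-class], most significant first.
#' @param config a [gvConfig()] list.
#' @return a [ValidationVerdict-class] named `length_cluster`.
#' @export
validateLengthCluster <- function(query, hits, config = gvConfig()) {
  if (length(hits) < 5L)
    return(.skip("length_cluster", "too few hits (need 5)"))
  lens <- sort(vapply(hits, function(h) h@length, integer(1)))
  gapCut <- max(config$clusterGapMin, config$clusterGapFrac * stats::median(lens))
  cuts <- which(diff(lens) > gapCut)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, length(lens))
  clusters <- data.frame(lo = lens[starts], hi = lens[ends],
                         n = ends - starts + 1L)
  main <- clusters[order(-clusters$n, clusters$hi - clusters$lo,
                         clusters$lo), ][1L, ]
  t <- config$lengthTolerance
  accepted <- c(main$lo * (1 - t), main$hi * (1 + t))
  qlen <- .queryLenAA(query)
  ok <- qlen >= accepted[1L] && qlen <= accepted[2L]
  plot <- new("PlotPayload", kind = "length_histogram",
              series = list(hit_lengths = as.numeric(lens)),
              annotations = list(query_length = qlen,
                                 main_lo = main$lo, main_hi = main$hi))
  .newVerdict("length_cluster", if (ok) "pass" else "fail",
              statistic = qlen, threshold = accepted,
              message = sprintf(
                "query length %d aa %s the main hit-length cluster interval [%.1f, %.1f]",
                qlen, if (ok) "lies within" else "lies outside",
                accepted[1L], accepted[2L]),
              plot = plot)
}

#' Length validation by rank of the query among hit lengths
#'
#' The query length's fractional rank among the hit lengths (ties counted
#' half) flags the prediction as too short below `rankLow` and too long
#' above `rankHigh`.
#'
#' @inheritParams validateLengthCluster
#' @return a [ValidationVerdict-class] named `length_rank`.
#' @export
validateLengthRank <- function(query, hits, config = gvConfig()) {
  if (length(hits) < 5L)
    return(.skip("length_rank", "too few hits (need 5)"))
  lens <- vapply(hits, function(h) h@length, integer(1))
  qlen <- .queryLenAA(query)
  r <- (sum(lens < qlen) + 0.5 * sum(lens == qlen)) / length(lens)
  status <- if (r < config$rankLow || r > config$rankHigh) "fail" else "pass"
  msg <- if (r < config$rankLow)
    sprintf("length rank %.2f: query looks too short", r)
  else if (r > config$rankHigh)
    sprintf("length rank %.2f: query looks too long", r)
  else sprintf("length rank %.2f is unremarkable", r)
  .newVerdict("length_rank", status, statistic = r,
              threshold = c(config$rankLow, config$rankHigh), message = msg)
}

#' Duplication validation (Wilcoxon coverage test)
#'
#' For each of the most significant hits, per-position coverage counts over
#' the hit's residues are accumulated from that hit's HSP hit-side
#' intervals; covered positions are pooled across hits and a one-sample
#' Wilcoxon signed-rank test of median coverage = 1 against > 1 flags
#' regions of the hits matched by the query more than once (e.g. a merged
#' tandem duplicate).
#'
#' @inheritParams validateLengthCluster
#' @return a [ValidationVerdict-class] named `duplication`.
#' @export
validateDuplication <- function(query, hits, config = gvConfig()) {
  if (!length(hits)) return(.skip("duplication", "no hits"))
  top <- .topHits(hits, config$topHits)
  plot <- .hitOverviewPayload(query, top)
  multi <- any(vapply(top, function(h) nrow(h@hsps) >= 2L, logical(1)))
  if (!multi)
    return(.newVerdict("duplication", "pass", statistic = 1,
                       threshold = config$duplicationAlpha,
                       message = "no multi-HSP hit; nothing matched twice",
                       plot = plot))
  pooled <- numeric()
  for (h in top) {
    cov <- integer(h@length)
    for (i in seq_len(nrow(h@hsps)))
      cov[(h@hsps$hStart[i] + 1L):h@hsps$hEnd[i]] <-
        cov[(h@hsps$hStart[i] + 1L):h@hsps$hEnd[i]] + 1L
    pooled <- c(pooled, cov[cov >= 1L])
  }
  if (all(pooled == 1))
    return(.newVerdict("duplication", "pass", statistic = 1,
                       threshold = config$duplicationAlpha,
                       message = "all hit positions covered exactly once",
                       plot = plot))
  test <- signedRankTest(pooled, mu = 1)
  status <- if (!is.na(test$p) && test$p < config$duplicationAlpha)
    "fail" else "pass"
  .newVerdict("duplication", status, statistic = mean(pooled),
              threshold = config$duplicationAlpha, pValue = test$p,
              message = sprintf(
                "mean coverage of covered hit positions %.2f (Wilcoxon p = %.3g): %s",
                mean(pooled), test$p,
                if (status == "fail") "hit regions matched more than once"
                else "no excess coverage"),
              plot = plot)
}

.hitOverviewPayload <- function(query, hits) {
  hs <- do.call(rbind, lapply(seq_along(hits), function(i) {
    h <- hits[[i]]@hsps
    data.frame(hit = i, qStart = h$qStart, qEnd = h$qEnd)
  }))
  new("PlotPayload", kind = "hit_overview",
      series = list(hit = as.numeric(hs$hit),
                    q_start = as.numeric(hs$qStart),
                    q_end = as.numeric(hs$qEnd)),
      annotations = list(query_length = nchar(query@residues),
                         n_hits = length(hits)))
}

#' Conserved-regions validation against a hit profile
#'
#' The ten most significant hits with recoverable sequences are multiply
#' aligned, summarised as a position-specific scoring profile, and the
#' query (or, for nucleotide queries, the translation of its longest ORF)
#' is globally aligned to that profile by log-odds scoring.  Runs of at
#' least `conservedRunLen` core profile columns deleted from the query
#' count as missing regions; runs of query residues aligned to gap or
#' non-core columns count as extra regions.  The verdict fails when the
#' total missing plus extra columns exceed `conservedMaxFrac` of the core
#' profile length.
#'
#' @inheritParams validateLengthCluster
#' @param hitFasta optional named character vector of full hit residues.
#' @return a [ValidationVerdict-class] named `conserved_regions`.
#' @export
validateConservedRegions <- function(query, hits, config = gvConfig(),
                                     hitFasta = NULL) {
  if (length(hits) < 2L)
    return(.skip("conserved_regions", "too few hits (need 2)"))
  seqs <- hitSequences(hits, hitFasta)
  seqs <- seqs[!is.na(seqs) & nzchar(seqs)]
  if (length(seqs) < 2L)
    return(.skip("conserved_regions",
                 "hit sequences not recoverable (need aligned hit strings or a hit FASTA)"))
  if (length(seqs) > config$profileMaxSeqs)
    seqs <- seqs[seq_len(config$profileMaxSeqs)]
  queryRes <- if (query@alphabet == "protein") query@residues
              else .translateLongestOrf(query@residues, config$minOrfLen)
  if (is.null(queryRes))
    return(.skip("conserved_regions", "no ORF to translate"))
  queryRes <- gsub("[*]", "X", queryRes)
  aln <- multipleAlign(unname(seqs), config$gapOpen, config$gapExtend)
  profile <- buildProfile(aln)
  path <- alignToProfile(profile, queryRes, config$gapOpen, config$gapExtend)
  core <- profile@core
  coreLen <- sum(core)
  if (coreLen == 0L)
    return(.newVerdict("conserved_regions", "error",
                       message = "profile has no core columns"))
  isMissing <- path[, 1L] > 0L & path[, 2L] == 0L & core[pmax(path[, 1L], 1L)]
  isExtra <- path[, 2L] > 0L &
    (path[, 1L] == 0L | !core[pmax(path[, 1L], 1L)])
  runCols <- function(flag) {
    r <- rle(flag)
    sum(r$lengths[r$values & r$lengths >= config$conservedRunLen])
  }
  bad <- runCols(isMissing) + runCols(isExtra)
  statistic <- bad / coreLen
  state <- integer(nrow(path))          # 0 ok, 1 non-core, 2 missing, 3 extra
  state[path[, 1L] > 0L & !core[pmax(path[, 1L], 1L)]] <- 1L
  state[isMissing] <- 2L
  state[isExtra] <- 3L
  plot <- new("PlotPayload", kind = "conserved_map",
              series = list(state = as.numeric(state)),
              annotations = list(n_profile_seqs = profile@nSeqs,
                                 core_length = coreLen))
  status <- if (statistic > config$conservedMaxFrac) "fail" else "pass"
  .newVerdict("conserved_regions", status, statistic = statistic,
              threshold = config$conservedMaxFrac,
              message = sprintf(
                "%d of %d core profile columns missing or extra (fraction %.2f)%s",
                bad, coreLen, statistic,
                if (status == "fail") ": query deviates from the hit profile"
                else ""),
              plot = plot)
}

#' Gene-merge validation (weighted start-stop regression)
#'
#' When the HSP start and stop coordinates on the query both deviate from
#' unimodality, the HSPs map to multiple query regions; a weighted linear
#' regression of HSP stop on HSP start (weights -log10 of the HSP e-value)
#' with a slope inside the empirical window [0.4, 1.2] then flags the
#' prediction as a merge of two genes.
#'
#' @inheritParams validateLengthCluster
#' @return a [ValidationVerdict-class] named `gene_merge`.
#' @export
validateGeneMerge <- function(query, hits, config = gvConfig()) {
  top <- .topHits(hits, config$topHits)
  hs <- .pooledHsps(top)
  if (is.null(hs) || nrow(hs) < 4L)
    return(.skip("gene_merge", "too few HSPs (need 4)"))
  starts <- hs$qStart
  stops <- hs$qEnd
  w <- -log10(hs$evalue + 1e-250)
  fit <- wlsFit(starts, stops, w)
  slope <- if (is.na(fit$slope)) 0 else fit$slope
  plot <- new("PlotPayload", kind = "hsp_offsets",
              series = list(q_start = as.numeric(starts),
                            q_end = as.numeric(stops),
                            weight = as.numeric(w)),
              annotations = list(slope = slope,
                                 intercept = if (is.na(fit$intercept)) 0
                                             else fit$intercept,
                                 query_length = nchar(query@residues)))
  if (unimodalityCheck(starts) && unimodalityCheck(stops))
    return(.newVerdict("gene_merge", "pass", statistic = slope,
                       threshold = c(config$mergeSlopeLow, config$mergeSlopeHigh),
                       message = "HSP coordinates are unimodal: hits map to one region",
                       plot = plot))
  if (is.na(fit$slope))
    return(.newVerdict("gene_merge", "pass", statistic = 0,
                       threshold = c(config$mergeSlopeLow, config$mergeSlopeHigh),
                       message = "degenerate HSP geometry (all starts equal); no regression",
                       plot = plot))
  merged <- slope >= config$mergeSlopeLow & slope <= config$mergeSlopeHigh
  .newVerdict("gene_merge", if (merged) "fail" else "pass",
              statistic = slope,
              threshold = c(config$mergeSlopeLow, config$mergeSlopeHigh),
              message = sprintf(
                "bimodal HSP coordinates; weighted start-stop regression slope %.2f %s the merge window [%.1f, %.1f]",
                slope, if (merged) "inside" else "outside",
                config$mergeSlopeLow, config$mergeSlopeHigh),
              plot = plot)
}

.orfTracksPayload <- function(query, orfs, config) {
  tab <- .orfTable(orfs)
  new("PlotPayload", kind = "orf_tracks",
      series = list(frame = as.numeric(match(tab$frame,
                                             c("+1", "+2", "+3", "-1", "-2", "-3"))),
                    start = as.numeric(tab$start),
                    end = as.numeric(tab$end)),
      annotations = list(query_length = nchar(query@residues),
                         min_orf_len = config$minOrfLen))
}

#' Ab initio ORF validation
#'
#' A correct coding prediction has a single major ORF; frameshifts,
#' retained introns or merged genes show up as several.  Major ORFs are
#' those at least `majorOrfRatio` of the longest ORF's length.
#'
#' @inheritParams validateLengthCluster
#' @return a [ValidationVerdict-class] named `orf_ab_initio`.
#' @export
validateOrfAbInitio <- function(query, config = gvConfig()) {
  if (query@alphabet != "nucleotide")
    return(.skip("orf_ab_initio", "protein query: no reading frames"))
  orfs <- findOrfs(query@residues, config$minOrfLen)
  tab <- .orfTable(orfs)
  plot <- .orfTracksPayload(query, orfs, config)
  if (!nrow(tab))
    return(.newVerdict("orf_ab_initio", "fail", statistic = 0, threshold = 1,
                       message = sprintf("no ORF of at least %d nt", config$minOrfLen),
                       plot = plot))
  nMajor <- sum(tab$length >= config$majorOrfRatio * max(tab$length))
  .newVerdict("orf_ab_initio", if (nMajor == 1L) "pass" else "fail",
              statistic = nMajor, threshold = 1,
              message = sprintf("%d major ORF(s); a clean prediction has exactly one",
                                nMajor),
              plot = plot)
}

#' Similarity-based ORF validation
#'
#' All BLAST hits are expected to align within a single ORF; the statistic
#' is the largest fraction of the HSP-covered nucleotides falling inside
#' one ORF.  HSPs in disagreeing frames force the statistic below 1.
#'
#' @inheritParams validateLengthCluster
#' @return a [ValidationVerdict-class] named `orf_similarity`.
#' @export
validateOrfSimilarity <- function(query, hits, config = gvConfig()) {
  if (query@alphabet != "nucleotide")
    return(.skip("orf_similarity", "protein query: no reading frames"))
  if (!length(hits)) return(.skip("orf_similarity", "no hits"))
  hs <- .pooledHsps(.topHits(hits, config$topHits))
  covered <- IRanges::reduce(IRanges::IRanges(start = hs$qStart + 1L,
                                              end = hs$qEnd))
  total <- sum(IRanges::width(covered))
  if (total == 0L) return(.skip("orf_similarity", "no HSP coverage"))
  tab <- .orfTable(findOrfs(query@residues, config$minOrfLen))
  best <- 0
  if (nrow(tab)) {
    for (i in seq_len(nrow(tab))) {
      orf <- IRanges::IRanges(start = tab$start[i] + 1L, end = tab$end[i])
      ov <- sum(IRanges::width(IRanges::intersect(covered, orf)))
      best <- max(best, ov)
    }
  }
  statistic <- best / total
  status <- if (statistic >= config$orfSimilarityMin) "pass" else "fail"
  .newVerdict("orf_similarity", status, statistic = statistic,
              threshold = config$orfSimilarityMin,
              message = sprintf(
                "%.0f%% of HSP-covered nucleotides fall in a single ORF%s",
                100 * statistic,
                if (status == "fail") ": hits span multiple reading frames"
                else ""))
}

#' MAKER quality-index validation
#'
#' When the defline carries a MAKER QI tag, the mean of the available EST
#' support fractions (splice sites and exons confirmed by EST alignment)
#' must reach `makerQiMin`; -1 fields are unavailable and excluded.
#'
#' @param query a [SequenceRecord-class].
#' @param qi a `maker_qi` list from [parseMakerQI()], or NULL.
#' @param config a [gvConfig()] list.
#' @return a [ValidationVerdict-class] named `maker_qi`.
#' @export
validateMakerQI <- function(query, qi = parseMakerQI(query@defline),
                            config = gvConfig()) {
  if (is.null(qi)) return(.skip("maker_qi", "no QI tag in the defline"))
  vals <- c(qi$splice_est_frac, qi$exon_est_frac)
  vals <- vals[vals != -1]
  if (!length(vals))
    return(.skip("maker_qi", "EST support fields unavailable (-1)"))
  statistic <- mean(vals)
  status <- if (statistic >= config$makerQiMin) "pass" else "fail"
  .newVerdict("maker_qi", status, statistic = statistic,
              threshold = config$makerQiMin,
              message = sprintf("mean EST support %.2f %s %.2f",
                                statistic,
                                if (status == "pass") "reaches" else "below",
                                config$makerQiMin))
}
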