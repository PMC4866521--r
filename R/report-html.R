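.htmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

.num <- function(x) {
  x[!is.finite(x)] <- 0
  formatC(x, format = "f", digits = 2, drop0trailing = TRUE)
}

# linear map of data values onto pixel coordinates
.scaler <- function(lo, hi, pixLo, pixHi) {
  span <- hi - lo
  if (!is.finite(span) || span <= 0) span <- 1
  function(v) pixLo + (v - lo) / span * (pixHi - pixLo)
}

.svgOpen <- function(w, h, title) {
  sprintf(paste0(
    "<svg class=\"gv-plot\" viewBox=\"0 0 %d %d\" width=\"%d\" height=\"%d\"",
    " xmlns=\"http://www.w3.org/2000/svg\" role=\"img\">",
    "<title>%s</title>",
    "<rect x=\"0\" y=\"0\" width=\"%d\" height=\"%d\" fill=\"#fcfcfc\" stroke=\"#ccc\"/>"),
    w, h, w, h, .htmlEscape(title), w, h)
}

.svgLengthHistogram <- function(p) {
  w <- 380L; h <- 150L
  lens <- p@series$hit_lengths
  q <- as.numeric(p@annotations$query_length)
  br <- pretty(c(lens, q), n = 12)
  hs <- graphics::hist(lens, breaks = br, plot = FALSE)
  sx <- .scaler(min(br), max(br), 30, w - 10)
  sy <- .scaler(0, max(hs$counts, 1), h - 20, 10)
  bars <- vapply(seq_along(hs$counts), function(i) {
    x0 <- sx(hs$breaks[i]); x1 <- sx(hs$breaks[i + 1L]); y <- sy(hs$counts[i])
    sprintf("<rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"#7aa6c2\"/>",
            .num(x0), .num(y), .num(max(x1 - x0 - 1, 0.5)),
            .num(max(h - 20 - y, 0)))
  }, character(1))
  marker <- sprintf(
    "<line x1=\"%s\" y1=\"10\" x2=\"%s\" y2=\"%d\" stroke=\"#c0392b\" stroke-width=\"2\"/>",
    .num(sx(q)), .num(sx(q)), h - 20L)
  paste0(.svgOpen(w, h, "hit length distribution with query length marker"),
         paste(bars, collapse = ""), marker, "</svg>")
}

.svgHspOffsets <- function(p) {
  w <- 380L; h <- 150L
  s <- p@series
  qlen <- max(as.numeric(p@annotations$query_length), s$q_end, 1)
  sx <- .scaler(0, qlen, 30, w - 10)
  n <- length(s$q_start)
  sy <- .scaler(0, max(n, 1), 15, h - 15)
  segs <- vapply(seq_len(n), function(i) sprintf(
    "<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"#2c6e49\" stroke-width=\"3\"/>",
    .num(sx(s$q_start[i])), .num(sy(i - 0.5)),
    .num(sx(s$q_end[i])), .num(sy(i - 0.5))), character(1))
  paste0(.svgOpen(w, h, "HSP start/stop offsets on the query"),
         paste(segs, collapse = ""), "</svg>")
}

.svgHitOverview <- function(p) {
  w <- 380L; h <- 150L
  s <- p@series
  qlen <- max(as.numeric(p@annotations$query_length), s$q_end, 1)
  sx <- .scaler(0, qlen, 30, w - 10)
  nh <- max(s$hit, 1)
  sy <- .scaler(0, nh, 15, h - 15)
  rects <- vapply(seq_along(s$hit), function(i) sprintf(
    "<rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"4\" fill=\"#5b5ea6\"/>",
    .num(sx(s$q_start[i])), .num(sy(s$hit[i] - 0.5)),
    .num(max(sx(s$q_end[i]) - sx(s$q_start[i]), 0.5))), character(1))
  paste0(.svgOpen(w, h, "hit regions mapped on the query"),
         paste(rects, collapse = ""), "</svg>")
}

.svgConservedMap <- function(p) {
  w <- 380L; h <- 70L
  st <- p@series$state
  n <- max(length(st), 1)
  sx <- .scaler(0, n, 10, w - 10)
  cols <- c("#2c6e49", "#bbbbbb", "#c0392b", "#e67e22")  # ok/non-core/missing/extra
  cells <- vapply(seq_along(st), function(i) sprintf(
    "<rect x=\"%s\" y=\"20\" width=\"%s\" height=\"30\" fill=\"%s\"/>",
    .num(sx(i - 1)), .num(max(sx(i) - sx(i - 1), 0.3)),
    cols[st[i] + 1L]), character(1))
  paste0(.svgOpen(w, h, "conserved-region map: query vs hit profile"),
         paste(cells, collapse = ""), "</svg>")
}

.svgOrfTracks <- function(p) {
  w <- 380L; h <- 170L
  s <- p@series
  qlen <- max(as.numeric(p@annotations$query_length), 1)
  sx <- .scaler(0, qlen, 30, w - 10)
  sy <- .scaler(0, 6, 15, h - 15)
  labels <- vapply(1:6, function(f) sprintf(
    "<text x=\"4\" y=\"%s\" font-size=\"9\">%s</text>",
    .num(sy(f - 0.3)), c("+1", "+2", "+3", "-1", "-2", "-3")[f]),
    character(1))
  rects <- if (length(s$frame)) vapply(seq_along(s$frame), function(i) sprintf(
    "<rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"8\" fill=\"#b07aa1\"/>",
    .num(sx(s$start[i])), .num(sy(s$frame[i] - 0.65)),
    .num(max(sx(s$end[i]) - sx(s$start[i]), 0.5))), character(1))
  else character()
  paste0(.svgOpen(w, h, "open reading frames in the six frames"),
         paste(labels, collapse = ""), paste(rects, collapse = ""), "</svg>")
}

.renderPayloadSvg <- function(p) {
  switch(p@kind,
         length_histogram = .svgLengthHistogram(p),
         hsp_offsets = .svgHspOffsets(p),
         hit_overview = .svgHitOverview(p),
         conserved_map = .svgConservedMap(p),
         orf_tracks = .svgOrfTracks(p))
}

ANALYSIS_EXPLANATIONS <- c(
  length_cluster = "Compares the query length with the lengths of the most significant hits, clustered into length groups; the query should fall inside the densest group.",
  length_rank = "Rank of the query length among hit lengths; a very low or high rank suggests the prediction is too short or too long.",
  duplication = "Wilcoxon test of whether hit regions are matched by the query more than once, e.g. after merging tandem duplicates.",
  conserved_regions = "Aligns the query to a scoring profile of the top ten hits to expose missing or extra regions.",
  gene_merge = "Checks HSP start/stop coordinates for bimodality; a weighted regression slope near one then indicates two genes merged into one model.",
  orf_ab_initio = "Scans the six reading frames: a clean coding prediction has a single major open reading frame.",
  orf_similarity = "All BLAST hits are expected to align inside one open reading frame.",
  maker_qi = "MAKER's defline quality index: mean fraction of splice sites and exons confirmed by EST evidence.")

HTML_CSS <- paste(
  "body{font-family:sans-serif;margin:1.5em;color:#222}",
  "table{border-collapse:collapse}",
  "td,th{border:1px solid #ccc;padding:3px 8px;font-size:13px}",
  "tr.fail td.score{background:#f7d4cf}",
  "tr.pass td.score{background:#d5e8d4}",
  ".verdict{margin:2px 0;font-size:13px}",
  ".status-pass{color:#2c6e49;font-weight:bold}",
  ".status-fail{color:#c0392b;font-weight:bold}",
  ".status-skipped,.status-error,.status-unsure{color:#777}",
  ".gv-plot{margin:4px 8px 4px 0}",
  "section{border-top:2px solid #eee;margin-top:1.5em;padding-top:0.5em}",
  sep = "")

#' Write the self-contained HTML report
#'
#' A single file with inline CSS and inline SVG graphs (no scripts, no
#' network fetches): a summary table of all queries sorted by score, then
#' one section per query with up to five graphs (hit-length histogram with
#' query marker, HSP start/stop offsets, hit-region overview,
#' conserved-region map, and - for nucleotide queries - ORF tracks) plus a
#' textual explanation of every analysis outcome.
#'
#' @param reports list of [QueryReport-class].
#' @param path output file.
#' @param timestamp run timestamp string; pass a fixed value for
#'   reproducible output.
#' @return the path, invisibly.
#' @export
renderHtml <- function(reports, path,
                       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")) {
  scores <- vapply(reports, function(r)
    if (is.na(r@score)) -1 else as.numeric(r@score), numeric(1))
  ordSummary <- order(scores, decreasing = TRUE)
  sumRows <- vapply(ordSummary, function(i) {
    r <- reports[[i]]
    cls <- if (!is.na(r@score) && r@score < 50) "fail" else "pass"
    sprintf(paste0(
      "<tr class=\"%s\"><td><a href=\"#q-%s\">%s</a></td>",
      "<td class=\"score\">%s</td><td>%d</td></tr>"),
      cls, .htmlEscape(r@queryId), .htmlEscape(r@queryId),
      if (is.na(r@score)) "&ndash;" else as.character(r@score), r@nHits)
  }, character(1))
  sections <- vapply(reports, function(r) {
    head <- sprintf(
      "<section id=\"q-%s\"><h2>%s <small>score %s, %d hit(s)</small></h2>",
      .htmlEscape(r@queryId), .htmlEscape(r@queryId),
      if (is.na(r@score)) "&ndash;" else as.character(r@score), r@nHits)
    if (r@nHits == 0L) {
      body <- "<p>no hits; analyses skipped</p>"
    } else body <- ""
    plots <- character()
    seen <- character()
    lines <- vapply(r@verdicts, function(v) {
      if (!is.null(v@plot) && !(v@plot@kind %in% seen)) {
        seen <<- c(seen, v@plot@kind)
        plots <<- c(plots, .renderPayloadSvg(v@plot))
      }
      sprintf(paste0(
        "<p class=\"verdict\"><span class=\"status-%s\">[%s]</span> ",
        "<b>%s</b>: %s<br/><i>%s</i></p>"),
        v@status, v@status, v@name, .htmlEscape(v@message),
        .htmlEscape(unname(ANALYSIS_EXPLANATIONS[v@name])))
    }, character(1))
    paste0(head, body, paste(plots[seq_len(min(length(plots), 5L))],
                             collapse = ""),
           paste(lines, collapse = ""), "</section>")
  }, character(1))
  html <- paste0(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\"/>",
    "<title>gene prediction quality report</title>",
    "<style>", HTML_CSS, "</style></head><body>",
    "<h1>Gene prediction quality report</h1>",
    sprintf("<p>%d quer%s &middot; generated %s</p>", length(reports),
            if (length(reports) == 1L) "y" else "ies",
            .htmlEscape(timestamp)),
    "<table><tr><th>query</th><th>score</th><th>hits</th></tr>",
    paste(sumRows, collapse = ""), "</table>",
    paste(sections, collapse = ""),
    "</body></html>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(html, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
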