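#' One-sample Wilcoxon signed-rank test (one-sided, greater)
#'
#' Tests H0: median = `mu` against median > `mu`.  Differences equal to
#' zero are dropped; absolute differences are midranked.  For `n` up to
#' `exactMax` non-zero differences the p-value is exact, computed from the
#' full null distribution of the positive-rank sum under sign symmetry
#' (a subset-sum convolution over the doubled midranks, which handles
#' ties exactly); for larger `n` a normal approximation with tie
#' correction and a 0.5 continuity correction is used.
#'
#' @param values numeric observations.
#' @param mu null median.
#' @param exactMax largest number of non-zero differences for which the
#'   exact distribution is enumerated.
#' @return list with `statistic` (positive-rank sum W+), `p` (NA when no
#'   non-zero difference remains) and `n` (non-zero differences used).
#' @export
signedRankTest <- function(values, mu = 1, exactMax = 25L) {
  d <- values - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(statistic = NA_real_, p = NA_real_, n = 0L))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exactMax) {
    r2 <- as.integer(round(2 * r))        # doubled midranks are integers
    tot <- sum(r2)
    f <- numeric(tot + 1L)                # f[s+1] = #subsets with sum s
    f[1L] <- 1
    for (x in r2) {
      shifted <- c(numeric(x), f[seq_len(tot + 1L - x)])
      f <- f + shifted
    }
    W2 <- as.integer(round(2 * W))
    p <- sum(f[(W2 + 1L):(tot + 1L)]) / 2^n
  } else {
    mean0 <- n * (n + 1) / 4
    ties <- table(r)
    var0 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (W - mean0 - 0.5) / sqrt(var0)
    p <- stats::pnorm(z, lower.tail = FALSE)
  }
  list(statistic = W, p = min(max(p, 0), 1), n = n)
}

#' Weighted least-squares line fit
#'
#' Fits `y = intercept + slope * x` by weighted least squares via
#' [stats::lm()].
#'
#' @param x,y numeric vectors of equal length.
#' @param w positive weights.
#' @return list with `slope` and `intercept`; both NA when fewer than two
#'   distinct x values are present.
#' @export
wlsFit <- function(x, y, w = rep(1, length(x))) {
  stopifnot(length(x) == length(y), length(w) == length(x), all(w > 0))
  if (length(unique(x)) < 2L)
    return(list(slope = NA_real_, intercept = NA_real_))
  fit <- stats::lm(y ~ x, weights = w)
  co <- stats::coef(fit)
  list(slope = unname(co[2L]), intercept = unname(co[1L]))
}

#' Largest-gap unimodality check
#'
#' Splits sorted values at the largest adjacent gap into two candidate
#' clusters and declares the sample bimodal when the gap between the
#' cluster means exceeds twice the larger within-cluster standard
#' deviation (floored at 1 query unit) and both clusters hold at least two
#' values.  Fewer than four values count as unimodal (insufficient
#' evidence).
#'
#' @param values numeric vector.
#' @return TRUE when unimodal (or not enough data), FALSE when bimodal.
#' @export
unimodalityCheck <- function(values) {
  if (length(values) < 4L) return(TRUE)
  v <- sort(values)
  gaps <- diff(v)
  k <- which.max(gaps)
  left <- v[seq_len(k)]
  right <- v[(k + 1L):length(v)]
  if (length(left) < 2L || length(right) < 2L) return(TRUE)
  sdFloor <- function(x) max(stats::sd(x), 1)
  sep <- mean(right) - mean(left)
  !(sep > 2 * max(sdFloor(left), sdFloor(right)))
}
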