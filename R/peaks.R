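# Local-extrema search with a topographic prominence criterion.
#
# The validity filter and the peak-count loss both need a deterministic peak
# detector with an explicit prominence threshold; the conventions are:
# plateaus contribute their first sample (earliest index wins), prominence is
# measured against the higher of the two flanking minima up to the nearest
# higher ground, and a refractory separation keeps only the tallest of any
# cluster of near-coincident peaks.

#' Find local maxima by prominence
#'
#' Detects interior local maxima of `x` whose topographic prominence is at
#' least `prominence`, optionally enforcing a minimum separation (the taller
#' peak of a close pair wins; ties go to the earlier index).
#'
#' @param x Numeric vector.
#' @param prominence Minimum prominence, on the scale of `x`
#'   (default 0.05, intended for \[0, 1\]-normalized windows).
#' @param min_sep Minimum separation between kept peaks, in samples
#'   (default 0 = no constraint).
#' @return Integer vector of peak indices (1-based), strictly increasing.
#' @export
find_peaks <- function(x, prominence = 0.05, min_sep = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  dx <- diff(x)
  # candidate maxima: rise before, fall after; plateau -> first sample of it
  cand <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) cand <- c(cand, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(cand)) return(integer(0))

  prom <- vapply(cand, function(p) .prominence(x, p), numeric(1))
  keep <- cand[prom >= prominence]
  if (length(keep) > 1L && min_sep > 0) {
    ord <- keep[order(x[keep], keep, decreasing = c(TRUE, FALSE),
                      method = "radix")]
    sel <- integer(0)
    for (p in ord)
      if (!length(sel) || all(abs(sel - p) >= min_sep)) sel <- c(sel, p)
    keep <- sort(sel)
  }
  keep
}

# prominence of the peak at index p: drop from x[p] to the higher of the two
# key saddles (lowest point between p and the nearest higher terrain on each
# side; signal end counts as higher terrain at -Inf guard).
.prominence <- function(x, p) {
  n <- length(x)
  left <- x[seq_len(p - 1L)]
  higher_l <- which(left > x[p])
  lmin <- if (length(higher_l)) min(x[(max(higher_l) + 1L):(p - 1L)])
          else min(left)
  right <- x[(p + 1L):n]
  higher_r <- which(right > x[p])
  rmin <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1L)])
          else min(right)
  x[p] - max(lmin, rmin)
}

#' Find local minima by prominence
#'
#' Convenience wrapper: minima of `x` are maxima of `-x`.
#'
#' @inheritParams find_peaks
#' @return Integer vector of trough indices (1-based).
#' @export
find_troughs <- function(x, prominence = 0.05, min_sep = 0) {
  find_peaks(-x, prominence = prominence, min_sep = min_sep)
}
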