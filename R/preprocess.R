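# The five-stage signal-processing pipeline: zero-phase Butterworth lowpass +
# DC removal, morphology-based invalid-segment removal, sliding-window
# segmentation, per-window min-max normalization, and augmentation. The
# filter runs forward-backward so fiducial timings are not shifted; sample
# counts are W = round(win_s * fs), S = round(stride_s * fs) with half-open
# windows [o, o + W) at 0-based offsets o = k * S.

#' Zero-phase Butterworth lowpass with DC removal
#'
#' Applies a Butterworth lowpass (default 5th order, 10 Hz cutoff)
#' forward-backward, then removes the mean (the DC component), keeping only
#' the pulsatile part of the signal.
#'
#' @param sig A [ppg_signal()].
#' @param order Filter order (per pass; the effective order doubles
#'   forward-backward).
#' @param cutoff_hz Cutoff frequency (Hz); requires `fs > 2 * cutoff_hz`.
#' @return A filtered, zero-mean [ppg_signal()].
#' @export
lowpass_dc_remove <- function(sig, order = 5, cutoff_hz = 10) {
  stopifnot(inherits(sig, "ppg_signal"))
  if (sig$fs <= 2 * cutoff_hz)
    stop("sampling rate ", sig$fs, " Hz too low for a ", cutoff_hz,
         " Hz cutoff", call. = FALSE)
  bf <- signal::butter(order, cutoff_hz / (sig$fs / 2), type = "low")
  x <- sig$samples - mean(sig$samples)
  # odd-reflection padding keeps the forward-backward pass free of edge
  # transients (value- and slope-continuous extension), then crop
  L <- length(x)
  np <- min(L - 1L, as.integer(ceiling(3 * sig$fs / cutoff_hz)))
  xp <- c(2 * x[1] - x[(np + 1L):2L], x, 2 * x[L] - x[(L - 1L):(L - np)])
  y <- signal::filtfilt(bf, xp)[(np + 1L):(np + L)]
  y <- y - mean(y)
  ppg_signal(y, fs = sig$fs, t0 = sig$t0)
}

#' Remove morphologically invalid segments from a synchronized pair
#'
#' Extracts valley-to-valley cycles from the reference stream, validates each
#' with [validate_cycle()], and removes invalid reference cycles together
#' with their synchronized distorted counterparts. Contiguous runs of valid
#' cycles are returned as fragments; windows are later formed only within
#' fragments, never across gaps.
#'
#' @param ref,dist Synchronized [ppg_signal()]s of equal length.
#' @param prominence Peak-detection prominence threshold.
#' @return A list: `fragments` (list of `list(reference, distorted, offset)`
#'   with `offset` the 0-based start of the fragment in the parent stream),
#'   `kept` (logical per cycle), `reasons` (character per cycle), and
#'   `onsets` (cycle boundary indices in the reference).
#' @export
remove_invalid_segments <- function(ref, dist, prominence = 0.05) {
  stopifnot(inherits(ref, "ppg_signal"), inherits(dist, "ppg_signal"))
  if (length(ref$samples) != length(dist$samples))
    stop("streams must be synchronized (equal length)", call. = FALSE)
  sf <- stream_fiducials(ref, prominence = prominence)
  if (!length(sf$cycles)) {
    warning("no detectable cycles in reference stream")
    return(list(fragments = list(), kept = logical(0),
                reasons = character(0), onsets = sf$onsets))
  }
  kept <- vapply(sf$cycles, `[[`, logical(1), "valid")
  reasons <- vapply(sf$cycles, `[[`, character(1), "reason")
  onsets <- sf$onsets

  fragments <- list()
  r <- rle(kept)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    i0 <- onsets[starts[j]]          # first sample of first valid cycle
    i1 <- onsets[ends[j] + 1L]       # next onset after last valid cycle
    fragments[[length(fragments) + 1L]] <- list(
      reference = ppg_signal(ref$samples[i0:i1], fs = ref$fs,
                             t0 = ref$t0 + (i0 - 1L) / ref$fs),
      distorted = ppg_signal(dist$samples[i0:i1], fs = dist$fs,
                             t0 = dist$t0 + (i0 - 1L) / dist$fs),
      offset = i0 - 1L)
  }
  list(fragments = fragments, kept = kept, reasons = reasons,
       onsets = onsets)
}

#' Segment a synchronized pair into sliding windows
#'
#' Windows of `round(win_s * fs)` samples are taken every
#' `round(stride_s * fs)` samples; the count per fragment is
#' `floor((L - W) / S) + 1`. Fragments shorter than one window yield no
#' windows (a message is emitted).
#'
#' @param ref,dist Synchronized [ppg_signal()]s (one contiguous fragment).
#' @param win_s Window length (s).
#' @param stride_s Stride (s).
#' @return A list of [window_pair()]s with 0-based `source_offset`s.
#' @export
window_pairs <- function(ref, dist, win_s = 8, stride_s = 1.6) {
  stopifnot(inherits(ref, "ppg_signal"), inherits(dist, "ppg_signal"))
  if (length(ref$samples) != length(dist$samples))
    stop("streams must be synchronized (equal length)", call. = FALSE)
  fs <- ref$fs
  W <- round(win_s * fs)
  S <- max(1L, round(stride_s * fs))
  L <- length(ref$samples)
  if (L < W) {
    message("fragment of ", L, " samples shorter than window (", W,
            "); skipped")
    return(list())
  }
  offs <- seq(0L, L - W, by = S)
  lapply(offs, function(o)
    window_pair(dist$samples[(o + 1L):(o + W)],
                ref$samples[(o + 1L):(o + W)],
                fs = fs, source_offset = o))
}

#' Min-max normalize a window pair
#'
#' Each channel is independently mapped to \[0, 1\]. A (near-)constant
#' channel (range below `tol`) has no defined normalization and raises a
#' `ppg_degenerate_window` error; [normalize_pairs()] drops such windows with
#' a message instead.
#'
#' @param w A [window_pair()].
#' @param tol Minimal channel range.
#' @return The normalized [window_pair()]; the original channel ranges are
#'   kept in attributes `scale_distorted` and `scale_reference`
#'   (`c(min, max)`).
#' @export
normalize_pair <- function(w, tol = 1e-6) {
  stopifnot(inherits(w, "window_pair"))
  norm1 <- function(x) {
    r <- range(x)
    if (diff(r) < tol)
      stop(structure(class = c("ppg_degenerate_window", "error", "condition"),
                     list(message = "degenerate (constant) window",
                          call = sys.call(-1))))
    list(x = (x - r[1]) / diff(r), scale = r)
  }
  d <- norm1(w$distorted)
  r <- norm1(w$reference)
  out <- window_pair(d$x, r$x, fs = w$fs, source_offset = w$source_offset,
                     subject = w$subject)
  attr(out, "scale_distorted") <- d$scale
  attr(out, "scale_reference") <- r$scale
  out
}

#' @rdname normalize_pair
#' @param pairs A list of [window_pair()]s.
#' @export
normalize_pairs <- function(pairs, tol = 1e-6) {
  out <- list()
  dropped <- 0L
  for (w in pairs) {
    nw <- tryCatch(normalize_pair(w, tol),
                   ppg_degenerate_window = function(e) NULL)
    if (is.null(nw)) dropped <- dropped + 1L
    else out[[length(out) + 1L]] <- nw
  }
  if (dropped > 0L)
    message(dropped, " degenerate window(s) dropped during normalization")
  out
}

# smooth monotone time warp shared by both channels; max local rate change
# `strength` (<= 0.05 by default usage)
make_warp <- function(n, strength) {
  u <- (seq_len(n) - 1) / (n - 1)
  k <- sample(1:3, 1)
  phi <- stats::runif(1, 0, 2 * pi)
  rate <- 1 + strength * sin(2 * pi * k * u + phi)
  pos <- cumsum(rate)
  (pos - pos[1]) / (pos[n] - pos[1])
}

#' Augment window pairs
#'
#' Produces `multiplier` augmented copies of each input pair using random
#' time warping (the identical smooth monotone warp is applied to both
#' channels so pairs stay synchronized), jittering (additive Gaussian noise),
#' baseline drift (additive slow sinusoid) and amplitude scaling, then
#' re-normalizes. With all magnitudes zero the output equals the input.
#'
#' @param pairs List of normalized [window_pair()]s.
#' @param ops Named list of magnitudes: `time_warp` (max local rate change,
#'   e.g. 0.05), `jitter` (noise SD), `baseline_drift` (amplitude),
#'   `amp_scale` (max relative scale change).
#' @param multiplier Integer >= 1; output count = `multiplier * length(pairs)`.
#' @param seed Integer RNG seed.
#' @return List of augmented, normalized [window_pair()]s.
#' @export
augment_pairs <- function(pairs,
                          ops = list(time_warp = 0.03, jitter = 0.01,
                                     baseline_drift = 0.05, amp_scale = 0.1),
                          multiplier = 1L, seed = 1L) {
  stopifnot(multiplier >= 1)
  defaults <- list(time_warp = 0, jitter = 0, baseline_drift = 0,
                   amp_scale = 0)
  ops <- utils::modifyList(defaults, as.list(ops))
  with_seed(seed, {
    out <- list()
    for (m in seq_len(multiplier)) {
      for (w in pairs) {
        n <- length(w$reference)
        u <- (seq_len(n) - 1) / (n - 1)
        ref <- w$reference
        dis <- w$distorted
        if (ops$time_warp > 0) {
          warp <- make_warp(n, ops$time_warp)
          ref <- stats::approx(u, ref, xout = warp, rule = 2)$y
          dis <- stats::approx(u, dis, xout = warp, rule = 2)$y
        }
        if (ops$jitter > 0) {
          ref <- ref + stats::rnorm(n, 0, ops$jitter)
          dis <- dis + stats::rnorm(n, 0, ops$jitter)
        }
        if (ops$baseline_drift > 0) {
          ref <- ref + ops$baseline_drift *
            sin(2 * pi * stats::runif(1, 0.5, 2) * u + stats::runif(1, 0, 2 * pi))
          dis <- dis + ops$baseline_drift *
            sin(2 * pi * stats::runif(1, 0.5, 2) * u + stats::runif(1, 0, 2 * pi))
        }
        if (ops$amp_scale > 0) {
          ref <- ref * (1 + stats::runif(1, -ops$amp_scale, ops$amp_scale))
          dis <- dis * (1 + stats::runif(1, -ops$amp_scale, ops$amp_scale))
        }
        aug <- window_pair(dis, ref, fs = w$fs,
                           source_offset = w$source_offset,
                           subject = w$subject)
        needs_norm <- ops$time_warp > 0 || ops$jitter > 0 ||
          ops$baseline_drift > 0 || ops$amp_scale > 0
        if (needs_norm)
          aug <- tryCatch(normalize_pair(aug),
                          ppg_degenerate_window = function(e) NULL)
        if (!is.null(aug)) out[[length(out) + 1L]] <- aug
      }
    }
    out
  })
}

#' Run the full preprocessing pipeline on one synchronized pair
#'
#' Filter + DC removal, invalid-segment removal on the reference, windowing
#' within valid fragments, and min-max normalization; per-stage counts are
#' returned in the `log` attribute.
#'
#' @param ref,dist Synchronized [ppg_signal()]s.
#' @param win_s,stride_s Window length and stride (s).
#' @param lowpass Apply the filtering stage.
#' @param validity_filter Apply invalid-segment removal.
#' @param prominence Peak-detection prominence.
#' @return A list of normalized [window_pair()]s with attribute `log`
#'   (`n_cycles`, `n_valid`, `n_fragments`, `n_windows`).
#' @export
preprocess_pair <- function(ref, dist, win_s = 8, stride_s = 1.6,
                            lowpass = TRUE, validity_filter = TRUE,
                            prominence = 0.05) {
  if (lowpass) {
    ref <- lowpass_dc_remove(ref)
    dist <- lowpass_dc_remove(dist)
  }
  if (validity_filter) {
    seg <- remove_invalid_segments(ref, dist, prominence)
    frags <- seg$fragments
    n_cycles <- length(seg$kept)
    n_valid <- sum(seg$kept)
  } else {
    frags <- list(list(reference = ref, distorted = dist, offset = 0L))
    n_cycles <- NA_integer_
    n_valid <- NA_integer_
  }
  out <- list()
  for (fr in frags) {
    ws <- window_pairs(fr$reference, fr$distorted, win_s, stride_s)
    ws <- normalize_pairs(ws)
    for (w in ws) {
      w$source_offset <- w$source_offset + fr$offset
      out[[length(out) + 1L]] <- w
    }
  }
  message(sprintf("preprocess: %s cycles (%s valid) -> %d fragment(s) -> %d window(s)",
                  n_cycles, n_valid, length(frags), length(out)))
  attr(out, "log") <- list(n_cycles = n_cycles, n_valid = n_valid,
                           n_fragments = length(frags),
                           n_windows = length(out))
  out
}
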