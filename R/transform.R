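# Continuous-stream enhancement: filter, window, normalize per window, run
# the generator, undo each window's min-max scaling, and recombine
# overlapping windows by Hann-weighted overlap-add, so the enhanced stream
# comes back on the input's amplitude scale with exactly the input's length.

#' Enhance a continuous signal with a trained generator
#'
#' The stream is (optionally) lowpass-filtered and DC-removed, segmented into
#' sliding windows, each window min-max normalized, transformed by the
#' generator, rescaled with its recorded (min, max), and recombined with
#' Hann-weighted overlap-add (weights are floored at a small epsilon so
#' non-overlapping segments are returned unchanged). A final window anchored
#' at the stream end is added when the stride does not tile the stream, so
#' every sample is covered.
#'
#' @param sig A [ppg_signal()].
#' @param model A trained `ppg_generator` (or a `ppg_fit`, whose generator is
#'   used).
#' @param win_s,stride_s Window length and stride (s).
#' @param lowpass Apply the filtering stage first.
#' @param order,cutoff_hz Filter settings (see [lowpass_dc_remove()]).
#' @return A [ppg_signal()] of the same length and sampling rate.
#' @export
enhance_signal <- function(sig, model, win_s = 8, stride_s = 1.6,
                           lowpass = TRUE, order = 5, cutoff_hz = 10) {
  stopifnot(inherits(sig, "ppg_signal"))
  if (inherits(model, "ppg_fit")) model <- model$generator
  stopifnot(inherits(model, "ppg_generator"))
  if (lowpass) sig <- lowpass_dc_remove(sig, order, cutoff_hz)
  fs <- sig$fs
  x <- sig$samples
  L <- length(x)
  W <- round(win_s * fs)
  S <- max(1L, round(stride_s * fs))
  if (L < W) {
    # single short window: the generator pads internally
    z <- enhance_window(model, .minmax(x)$x)
    sc <- .minmax(x)$scale
    return(ppg_signal(z * diff(sc) + sc[1], fs = fs, t0 = sig$t0))
  }
  offs <- seq(0L, L - W, by = S)
  if (offs[length(offs)] != L - W) offs <- c(offs, L - W)

  wins <- matrix(0, W, length(offs))
  scales <- matrix(0, 2, length(offs))
  degen <- logical(length(offs))
  for (i in seq_along(offs)) {
    seg <- x[(offs[i] + 1L):(offs[i] + W)]
    degen[i] <- diff(range(seg)) < 1e-9
    mm <- .minmax(seg)
    wins[, i] <- mm$x
    scales[, i] <- mm$scale
  }
  z <- generator_forward(model, wins)
  zs <- matrix(0, W, length(offs))
  for (i in seq_along(offs)) {
    zs[, i] <- if (degen[i]) x[(offs[i] + 1L):(offs[i] + W)]  # pass through
               else z[, i] * (scales[2, i] - scales[1, i]) + scales[1, i]
  }
  ppg_signal(overlap_add(zs, offs, L), fs = fs, t0 = sig$t0)
}

#' Hann-weighted overlap-add recombination
#'
#' Recombines windows into a continuous stream as the Hann-weighted average
#' of all windows covering each sample (weights floored at 1e-6 so samples
#' covered by a single window are returned unchanged). With identical
#' overlapping content the recombination is the identity; with
#' non-overlapping windows it is exact concatenation.
#'
#' @param wins `W x N` matrix of windows.
#' @param offsets 0-based start offsets (one per window).
#' @param length_out Total output length; every sample in
#'   `[1, length_out]` must be covered by at least one window.
#' @return Numeric vector of length `length_out`.
#' @export
overlap_add <- function(wins, offsets, length_out) {
  wins <- as.matrix(wins)
  W <- nrow(wins)
  stopifnot(length(offsets) == ncol(wins))
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(W) - 1) / (W - 1))
  wt <- hann + 1e-6
  num <- numeric(length_out)
  den <- numeric(length_out)
  for (i in seq_along(offsets)) {
    idx <- (offsets[i] + 1L):(offsets[i] + W)
    num[idx] <- num[idx] + wt * wins[, i]
    den[idx] <- den[idx] + wt
  }
  if (any(den == 0))
    stop("every output sample must be covered by a window", call. = FALSE)
  num / den
}

.minmax <- function(x, tol = 1e-9) {
  r <- range(x)
  if (diff(r) < tol) list(x = x * 0, scale = c(r[1], r[1] + 1))
  else list(x = (x - r[1]) / diff(r), scale = r)
}

#' Enhance a single normalized window
#'
#' Thin wrapper over [generator_forward()] for one window already in
#' \[0, 1\].
#'
#' @param model A `ppg_generator`.
#' @param w Numeric vector.
#' @return Numeric vector of the same length, values in (0, 1).
#' @export
enhance_window <- function(model, w) {
  as.numeric(generator_forward(model, as.numeric(w)))
}

#' Enhance a set of window pairs
#'
#' Runs the generator over the distorted channel of each pair (batched) and
#' returns the enhanced windows as a `T x N` matrix alongside the reference
#' and distorted matrices — the shape the evaluation functions consume.
#'
#' @param model A `ppg_generator` or `ppg_fit`.
#' @param pairs List of normalized [window_pair()]s.
#' @param batch_size Windows per forward batch.
#' @return A list of `T x N` matrices: `enhanced`, `reference`, `distorted`.
#' @export
enhance_pairs <- function(model, pairs, batch_size = 64L) {
  if (inherits(model, "ppg_fit")) model <- model$generator
  m <- pairs_to_matrices(pairs)
  n <- ncol(m$y)
  z <- matrix(0, nrow(m$y), n)
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(n, s + batch_size - 1L)
    z[, idx] <- generator_forward(model, m$y[, idx, drop = FALSE])
  }
  list(enhanced = z, reference = m$x, distorted = m$y)
}

#' Write / read a resolved run configuration
#'
#' Every command-line run records the fully resolved parameter set (including
#' seeds) next to its outputs, as YAML.
#'
#' @param config Named list.
#' @param path YAML file path.
#' @return `path` invisibly (`read_run_config` returns the list).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
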