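#' PPG signal container
#'
#' A `ppg_signal` is a numeric sample vector together with its sampling rate
#' and a start-time offset. All pipeline stages consume and produce this
#' container.
#'
#' @param samples Numeric vector of samples. Must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Start offset in seconds (default 0).
#' @return An object of class `ppg_signal` with fields `samples`, `fs`, `t0`.
#' @examples
#' s <- ppg_signal(sin(2 * pi * 1.2 * seq(0, 8, by = 1 / 128)), fs = 128)
#' s
#' @export
ppg_signal <- function(samples, fs, t0 = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("`samples` must be finite", call. = FALSE)
  structure(list(samples = samples, fs = fs, t0 = as.numeric(t0)),
            class = "ppg_signal")
}

#' @export
print.ppg_signal <- function(x, ...) {
  cat(sprintf("<ppg_signal> %d samples @ %g Hz (%.2f s), t0 = %g s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$t0))
  invisible(x)
}

#' @export
length.ppg_signal <- function(x) length(x$samples)

#' Sample times of a signal
#'
#' @param sig A [ppg_signal()].
#' @return Numeric vector of sample times in seconds.
#' @export
signal_times <- function(sig) {
  stopifnot(inherits(sig, "ppg_signal"))
  sig$t0 + (seq_along(sig$samples) - 1) / sig$fs
}

#' Read / write a signal as CSV
#'
#' The on-disk format is two columns, `time_s` and `value`, with a header.
#' The sampling rate is recovered from the median time step on read.
#'
#' @param path File path.
#' @param sig A [ppg_signal()].
#' @return `read_ppg_csv` returns a [ppg_signal()]; `write_ppg_csv` returns
#'   `path` invisibly.
#' @export
read_ppg_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df)))
    stop("expected columns `time_s` and `value` in ", path, call. = FALSE)
  dt <- stats::median(diff(df$time_s))
  ppg_signal(df$value, fs = 1 / dt, t0 = df$time_s[1])
}

#' @rdname read_ppg_csv
#' @export
write_ppg_csv <- function(sig, path) {
  stopifnot(inherits(sig, "ppg_signal"))
  utils::write.csv(
    data.frame(time_s = signal_times(sig), value = sig$samples),
    path, row.names = FALSE)
  invisible(path)
}

#' Synchronized window pair
#'
#' Holds one distorted window and its sample-synchronized reference window,
#' as produced by [window_pairs()]. After [normalize_pair()] both channels
#' lie in \[0, 1\].
#'
#' @param distorted,reference Numeric vectors of equal length.
#' @param fs Sampling rate (Hz).
#' @param source_offset 0-based start index of the window in its parent
#'   stream.
#' @param subject Optional subject label.
#' @return An object of class `window_pair`.
#' @export
window_pair <- function(distorted, reference, fs, source_offset = 0L,
                        subject = NA_character_) {
  distorted <- as.numeric(distorted)
  reference <- as.numeric(reference)
  if (length(distorted) != length(reference))
    stop("window channels must have equal length", call. = FALSE)
  structure(list(distorted = distorted, reference = reference, fs = fs,
                 source_offset = as.integer(source_offset),
                 subject = subject),
            class = "window_pair")
}

#' @export
print.window_pair <- function(x, ...) {
  cat(sprintf("<window_pair> %d samples @ %g Hz, offset %d%s\n",
              length(x$reference), x$fs, x$source_offset,
              if (is.na(x$subject)) "" else paste0(", subject ", x$subject)))
  invisible(x)
}
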