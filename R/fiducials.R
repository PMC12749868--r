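# Per-cycle fiducial geometry. One pulse cycle runs valley-to-valley; an
# ideal cycle shows, in order: the systolic peak (global maximum), the
# dicrotic notch (a local minimum), and the diastolic peak (a secondary local
# maximum whose height is 30-90% of the systolic peak). All indices here are
# 1-based R indices into the cycle (index 1 = onset, last index = next onset).

#' Detect pulse onsets (valleys) in a signal
#'
#' Period-anchored beat segmentation: systolic peaks are located first
#' (prominent maxima with a refractory separation of 0.7 of the beat period,
#' the period estimated from the autocorrelation over the physiological range
#' 30-220 beats/min), and each onset is then the minimum between consecutive
#' systolic peaks. The refractory window is what makes the segmentation
#' robust: the diastolic peak and dicrotic notch always fall well inside 0.7
#' of a period of their own systolic peak, so neither can masquerade as a
#' beat boundary, however prominent. Leading/trailing minima before the first
#' and after the last peak are included so edge cycles are not lost.
#'
#' @param sig A [ppg_signal()], or a numeric vector (then `fs` is required).
#' @param fs Sampling rate, if `sig` is a plain vector.
#' @param prominence Minimum systolic-peak prominence on the
#'   min-max-normalized stream (default 0.25).
#' @return Integer vector of onset indices (1-based), strictly increasing;
#'   may be empty (e.g. for a flat signal).
#' @export
detect_valleys <- function(sig, fs = NULL, prominence = 0.25) {
  if (inherits(sig, "ppg_signal")) {
    x <- sig$samples
    fs <- sig$fs
  } else {
    if (is.null(fs)) stop("`fs` is required for a plain vector", call. = FALSE)
    x <- as.numeric(sig)
  }
  n <- length(x)
  rng <- diff(range(x))
  if (!is.finite(rng) || rng < 1e-12 || n < 3L) return(integer(0))
  xn <- (x - min(x)) / rng

  # beat period from the autocorrelation in the 30-220 bpm band; take the
  # first prominent ACF peak rather than the global maximum, which can sit
  # on a multiple of the period when alternating cycle lengths misalign the
  # fundamental lag
  lag_min <- max(2L, round(fs * 60 / 220))
  lag_max <- min(n - 2L, round(fs * 60 / 30))
  period <- fs * 0.8
  if (lag_max > lag_min) {
    ac <- stats::acf(xn, lag.max = lag_max, plot = FALSE,
                     demean = TRUE)$acf[-1]
    band <- lag_min:lag_max
    best <- band[which.max(ac[band])]
    pk <- find_peaks(ac, prominence = 0.05)
    pk <- pk[pk >= lag_min & pk <= lag_max & ac[pk] >= 0.5 * ac[best]]
    period <- if (length(pk)) pk[1] else best
  }

  peaks <- find_peaks(xn, prominence = prominence,
                      min_sep = max(1L, round(0.7 * period)))
  if (length(peaks) < 1L) return(integer(0))

  v <- integer(0)
  lead <- max(1L, peaks[1] - round(period))
  if (lead < peaks[1])
    v <- lead + which.min(x[lead:peaks[1]]) - 1L
  if (length(peaks) >= 2L) {
    for (k in seq_len(length(peaks) - 1L)) {
      seg <- peaks[k]:peaks[k + 1L]
      v <- c(v, peaks[k] + which.min(x[seg]) - 1L)
    }
  }
  tail_end <- min(n, peaks[length(peaks)] + round(period))
  if (tail_end > peaks[length(peaks)]) {
    v <- c(v, peaks[length(peaks)] +
             which.min(x[peaks[length(peaks)]:tail_end]) - 1L)
  }
  v <- as.integer(sort(unique(v)))
  v[v >= 1L & v <= n]
}

#' Detect fiducial points of one pulse cycle
#'
#' Locates the systolic peak (global maximum, earliest index on ties), the
#' dicrotic notch (the most prominent local minimum after the systolic peak)
#' and the diastolic peak (the most prominent local maximum after the notch).
#' Absent features are reported as `NA`, never fabricated. Detection runs on
#' an amplitude-normalized copy of the cycle; reported amplitudes are the
#' cycle's own values.
#'
#' @param cycle Numeric vector spanning one cycle, onset to next onset.
#' @param fs Sampling rate (Hz).
#' @param prominence Prominence threshold on the normalized cycle
#'   (default 0.05).
#' @return An object of class `cycle_fiducials`: indices `onset_idx`,
#'   `sp_idx`, `dn_idx`, `dp_idx`, `next_onset_idx` (1-based, `NA` when
#'   undetected); amplitudes `SP`, `DN`, `DP`; time spans `SW`, `DW`, `NT`,
#'   `DT` (s); areas `SA`, `DA` (amplitude x s, trapezoidal, above the cycle
#'   minimum); peak/trough counts used by [validate_cycle()].
#' @export
detect_fiducials <- function(cycle, fs, prominence = 0.05) {
  cycle <- as.numeric(cycle)
  n <- length(cycle)
  if (n < 0.25 * fs)
    stop("cycle too short: ", n, " samples at ", fs, " Hz", call. = FALSE)

  lo <- min(cycle)
  rng <- max(cycle) - lo
  cn <- if (rng > 1e-12) (cycle - lo) / rng else cycle * 0

  sp <- which.max(cycle)
  maxima <- find_peaks(cn, prominence = prominence)
  troughs <- find_troughs(cn, prominence = prominence)
  if (!(sp %in% maxima)) maxima <- sort(c(maxima, sp))

  dn <- NA_integer_
  dp <- NA_integer_
  tr_after <- troughs[troughs > sp]
  if (length(tr_after)) {
    prom_tr <- vapply(tr_after, function(p) .prominence(-cn, p), numeric(1))
    dn <- tr_after[which.max(prom_tr)]
    pk_after <- maxima[maxima > dn]
    if (length(pk_after)) {
      prom_pk <- vapply(pk_after, function(p) .prominence(cn, p), numeric(1))
      dp <- pk_after[which.max(prom_pk)]
    }
  }

  dt_s <- 1 / fs
  base <- cycle - lo
  structure(list(
    onset_idx = 1L, sp_idx = sp, dn_idx = dn, dp_idx = dp,
    next_onset_idx = n,
    SP = cycle[sp],
    DN = if (is.na(dn)) NA_real_ else cycle[dn],
    DP = if (is.na(dp)) NA_real_ else cycle[dp],
    SW = (sp - 1L) * dt_s,
    DW = (n - sp) * dt_s,
    NT = if (is.na(dn)) NA_real_ else (dn - 1L) * dt_s,
    DT = if (is.na(dp)) NA_real_ else (dp - 1L) * dt_s,
    SA = .trapz(base[1:sp]) * dt_s,
    DA = .trapz(base[sp:n]) * dt_s,
    n_peaks = length(maxima),
    n_troughs = length(troughs),
    ratio_dp_sp = if (is.na(dp) || rng < 1e-12) NA_real_
                  else (cycle[dp] - lo) / (cycle[sp] - lo),
    fs = fs
  ), class = "cycle_fiducials")
}

.trapz <- function(y) {
  n <- length(y)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2)
}

#' @export
print.cycle_fiducials <- function(x, ...) {
  cat(sprintf(
    "<cycle_fiducials> sp=%d dn=%s dp=%s / %d samples @ %g Hz (DP/SP=%s)\n",
    x$sp_idx, x$dn_idx, x$dp_idx, x$next_onset_idx, x$fs,
    if (is.na(x$ratio_dp_sp)) "NA" else sprintf("%.2f", x$ratio_dp_sp)))
  invisible(x)
}

#' Classify a cycle as morphologically valid or not
#'
#' A cycle is valid when it shows exactly one systolic peak, exactly one
#' dicrotic notch and exactly one diastolic peak, in that order, with the
#' diastolic amplitude between 30% and 90% of the systolic amplitude
#' (inclusive bounds, measured above the cycle minimum). Extraneous prominent
#' peaks or notches invalidate the cycle.
#'
#' @param f A `cycle_fiducials` object from [detect_fiducials()].
#' @return A list with `valid` (logical) and `reason` (character; `""` when
#'   valid).
#' @export
validate_cycle <- function(f) {
  stopifnot(inherits(f, "cycle_fiducials"))
  fail <- function(reason) list(valid = FALSE, reason = reason)
  if (is.na(f$dn_idx)) return(fail("missing dicrotic notch"))
  if (is.na(f$dp_idx)) return(fail("missing diastolic peak"))
  if (f$n_peaks != 2L) return(fail("extraneous features: peaks"))
  if (f$n_troughs != 1L) return(fail("extraneous features: notches"))
  if (!(f$onset_idx < f$sp_idx && f$sp_idx < f$dn_idx &&
        f$dn_idx < f$dp_idx && f$dp_idx < f$next_onset_idx))
    return(fail("fiducials out of order"))
  if (f$ratio_dp_sp < 0.30) return(fail("diastolic too small"))
  if (f$ratio_dp_sp > 0.90) return(fail("diastolic too large"))
  list(valid = TRUE, reason = "")
}

#' Extract the per-cycle feature mapping
#'
#' Returns the nine waveform features used throughout evaluation: systolic
#' amplitude `SP`, systolic/diastolic widths `SW`, `DW` (s), notch amplitude
#' `DN` and time `NT`, diastolic amplitude `DP` and time `DT`, and the
#' systolic/diastolic areas `SA`, `DA` (trapezoidal, above the cycle
#' minimum). Missing fiducials yield `NA` entries.
#'
#' @param f A `cycle_fiducials` object.
#' @return Named numeric vector of length 9.
#' @export
cycle_features <- function(f) {
  stopifnot(inherits(f, "cycle_fiducials"))
  c(SP = f$SP, SW = f$SW, DW = f$DW, DN = f$DN, NT = f$NT,
    DP = f$DP, DT = f$DT, SA = f$SA, DA = f$DA)
}

#' Fiducials for every cycle of a stream
#'
#' Segments a stream at detected onsets and runs [detect_fiducials()] and
#' [validate_cycle()] on each cycle.
#'
#' @inheritParams detect_valleys
#' @return A list with `onsets` (indices) and `cycles`, a list of
#'   `cycle_fiducials` objects each carrying `$valid`, `$reason` and
#'   `$offset` (0-based index of the cycle onset in the stream).
#' @export
stream_fiducials <- function(sig, fs = NULL, prominence = 0.05) {
  if (inherits(sig, "ppg_signal")) {
    x <- sig$samples
    fs <- sig$fs
  } else {
    x <- as.numeric(sig)
    if (is.null(fs)) stop("`fs` is required for a plain vector", call. = FALSE)
  }
  v <- detect_valleys(x, fs)
  cycles <- list()
  if (length(v) >= 2L) {
    for (k in seq_len(length(v) - 1L)) {
      seg <- x[v[k]:v[k + 1L]]
      f <- tryCatch(detect_fiducials(seg, fs, prominence),
                    error = function(e) NULL)
      if (is.null(f)) next
      chk <- validate_cycle(f)
      f$valid <- chk$valid
      f$reason <- chk$reason
      f$offset <- v[k] - 1L
      cycles[[length(cycles) + 1L]] <- f
    }
  }
  list(onsets = v, cycles = cycles)
}

#' Per-cycle feature table of a stream
#'
#' @inheritParams stream_fiducials
#' @return A data.frame with one row per cycle: `offset` (0-based onset
#'   index), `valid`, `reason`, and the nine features of [cycle_features()].
#' @export
feature_table <- function(sig, fs = NULL, prominence = 0.05) {
  sf <- stream_fiducials(sig, fs, prominence)
  if (!length(sf$cycles)) {
    return(data.frame(offset = integer(0), valid = logical(0),
                      reason = character(0)))
  }
  feats <- t(vapply(sf$cycles, cycle_features, numeric(9)))
  data.frame(
    offset = vapply(sf$cycles, `[[`, integer(1), "offset"),
    valid = vapply(sf$cycles, `[[`, logical(1), "valid"),
    reason = vapply(sf$cycles, `[[`, character(1), "reason"),
    feats)
}
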