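# Downstream physiological estimators: valley-based heart rate, heart rate
# variability on valley-to-valley intervals (a surrogate for R-R intervals),
# and the waveform + rhythm feature vector used for blood-pressure
# regression.

#' Beat series from a signal
#'
#' @param sig A [ppg_signal()] (or numeric vector with `fs`).
#' @param fs Sampling rate for plain vectors.
#' @param prominence Valley-detection prominence (see [detect_valleys()]).
#' @return An object of class `beat_series`: `valley_times` (s, strictly
#'   increasing) and `intervals` (ms).
#' @export
beat_series <- function(sig, fs = NULL, prominence = 0.40) {
  if (inherits(sig, "ppg_signal")) {
    fs <- sig$fs
    t0 <- sig$t0
  } else t0 <- 0
  v <- detect_valleys(sig, fs, prominence)
  vt <- t0 + (v - 1) / fs
  structure(list(valley_times = vt, intervals = diff(vt) * 1000),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d valleys, mean interval %.1f ms\n",
              length(x$valley_times),
              if (length(x$intervals)) mean(x$intervals) else NA))
  invisible(x)
}

#' Estimate heart rate from a window
#'
#' `HR = 60 * (V - 1) / (t_last - t_first)` over the detected pulse valleys —
#' interval-normalized counting, which is unbiased for windows containing
#' partial cycles at the edges.
#'
#' @inheritParams beat_series
#' @return Heart rate in beats/min, or `NA` with fewer than 2 valleys.
#' @export
estimate_hr <- function(sig, fs = NULL, prominence = 0.40) {
  b <- beat_series(sig, fs, prominence)
  v <- b$valley_times
  if (length(v) < 2L) return(NA_real_)
  60 * (length(v) - 1) / (v[length(v)] - v[1])
}

#' Heart-rate-variability metrics from a beat series
#'
#' RMSSD is the root mean square of successive interval differences; SDRR the
#' interval standard deviation (sample, n-1 convention by default); PNN50 the
#' percentage of successive differences exceeding 50 ms; HF the spectral
#' power of the interval series in 0.15-0.4 Hz, estimated on a 4 Hz
#' linearly-interpolated, detrended interval tachogram via a smoothed
#' periodogram.
#'
#' @param b A `beat_series` (or numeric vector of intervals in ms).
#' @param sdrr_population Use the population (n) convention for SDRR.
#' @return A list: `RMSSD` (ms), `SDRR` (ms), `PNN50` (%), `HF` (ms^2);
#'   entries are `NA` when too few intervals are available (RMSSD/PNN50 need
#'   at least 3 intervals, HF at least 4 and 10 s of span).
#' @export
estimate_hrv <- function(b, sdrr_population = FALSE) {
  if (inherits(b, "beat_series")) {
    iv <- b$intervals
    vt <- b$valley_times
  } else {
    iv <- as.numeric(b)
    vt <- c(0, cumsum(iv)) / 1000
  }
  n <- length(iv)
  out <- list(RMSSD = NA_real_, SDRR = NA_real_, PNN50 = NA_real_,
              HF = NA_real_)
  if (n >= 2L) {
    out$SDRR <- if (sdrr_population) sqrt(mean((iv - mean(iv))^2))
                else stats::sd(iv)
  }
  if (n >= 3L) {
    d <- diff(iv)
    out$RMSSD <- sqrt(mean(d^2))
    out$PNN50 <- 100 * mean(abs(d) > 50)
  }
  span <- vt[length(vt)] - vt[2]
  if (n >= 4L && span >= 10) {
    ti <- seq(vt[2], vt[length(vt)], by = 1 / 4)
    x <- stats::approx(vt[-1], iv, xout = ti, rule = 2)$y
    sp <- stats::spec.pgram(stats::ts(x, frequency = 4), taper = 0.1,
                            detrend = TRUE, plot = FALSE)
    band <- sp$freq >= 0.15 & sp$freq <= 0.4
    df <- sp$freq[2] - sp$freq[1]
    out$HF <- sum(sp$spec[band]) * df
  }
  out
}

#' Blood-pressure feature vector for one window
#'
#' Averages per-cycle fiducial features over the window and appends rhythm
#' statistics. The always-available block is SP, pulse area PA (mean total
#' cycle area), PA/SP, SW, DW, meanRR, SDRR, RMSSD, PNN50, HF; when at least
#' half of the cycles carry a dicrotic notch and diastolic peak, the
#' diastolic block DN, NT, DP, DT, DT_minus_SW is added.
#'
#' @inheritParams beat_series
#' @return An object of class `bp_features` (named list); `diastolic_block`
#'   flags whether the optional features are present.
#' @export
bp_features <- function(sig, fs = NULL, prominence = 0.05) {
  sf <- stream_fiducials(sig, fs, prominence)
  if (length(sf$cycles) < 2L)
    stop("need at least 2 cycles for BP features", call. = FALSE)
  feats <- t(vapply(sf$cycles, cycle_features, numeric(9)))
  b <- beat_series(sig, fs)
  hrv <- estimate_hrv(b)
  pa <- mean(feats[, "SA"] + feats[, "DA"])
  sp <- mean(feats[, "SP"])
  out <- list(SP = sp, PA = pa, PA_over_SP = pa / sp,
              SW = mean(feats[, "SW"]), DW = mean(feats[, "DW"]),
              meanRR = mean(b$intervals), SDRR = hrv$SDRR,
              RMSSD = hrv$RMSSD, PNN50 = hrv$PNN50, HF = hrv$HF)
  have_dia <- !is.na(feats[, "DN"]) & !is.na(feats[, "DP"])
  if (mean(have_dia) >= 0.5) {
    dm <- feats[have_dia, , drop = FALSE]
    out$DN <- mean(dm[, "DN"])
    out$NT <- mean(dm[, "NT"])
    out$DP <- mean(dm[, "DP"])
    out$DT <- mean(dm[, "DT"])
    out$DT_minus_SW <- mean(dm[, "DT"] - dm[, "SW"])
    out$diastolic_block <- TRUE
  } else {
    out$diastolic_block <- FALSE
  }
  structure(out, class = "bp_features")
}

#' @export
print.bp_features <- function(x, ...) {
  v <- unlist(x[names(x) != "diastolic_block"])
  cat(sprintf("<bp_features> %d features%s\n", length(v),
              if (isTRUE(x$diastolic_block)) " (incl. diastolic block)" else ""))
  print(round(v, 4))
  invisible(x)
}

#' Per-window downstream table
#'
#' Applies [estimate_hr()], [estimate_hrv()] and [bp_features()] to each
#' window and binds the results into one data.frame (one row per window;
#' missing features are `NA`).
#'
#' @param windows List (or `T x N` matrix) of windows.
#' @param fs Sampling rate (Hz).
#' @param prominence Valley-detection prominence.
#' @return A data.frame.
#' @export
downstream_table <- function(windows, fs, prominence = 0.05) {
  wm <- if (is.list(windows)) sapply(windows, identity)
        else as.matrix(windows)
  cols <- c("HR", "RMSSD", "SDRR", "PNN50", "HF", "SP", "PA", "PA_over_SP",
            "SW", "DW", "meanRR", "DN", "NT", "DP", "DT", "DT_minus_SW")
  out <- as.data.frame(matrix(NA_real_, ncol(wm), length(cols),
                              dimnames = list(NULL, cols)))
  for (i in seq_len(ncol(wm))) {
    w <- wm[, i]
    out$HR[i] <- estimate_hr(w, fs)
    hrv <- estimate_hrv(beat_series(w, fs))
    out$RMSSD[i] <- hrv$RMSSD; out$SDRR[i] <- hrv$SDRR
    out$PNN50[i] <- hrv$PNN50; out$HF[i] <- hrv$HF
    bp <- tryCatch(bp_features(w, fs, prominence), error = function(e) NULL)
    if (!is.null(bp))
      for (nm in intersect(names(bp), cols))
        out[[nm]][i] <- bp[[nm]]
  }
  out
}
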