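# Waveform evaluation: overall metrics (MAE, path-normalized DTW, Pearson
# correlation), per-feature MAPE over ordinally matched cycles, skewness /
# kurtosis errors, and the diastolic recovery rate.

#' Dynamic time warping distance
#'
#' Full (unconstrained) DTW with absolute-difference local cost, computed by
#' dynamic programming in C. By default the optimal alignment cost is
#' normalized by the optimal path length so values are comparable across
#' window lengths.
#'
#' @param a,b Numeric vectors.
#' @param normalize Divide by the optimal path length?
#' @return Non-negative scalar.
#' @export
dtw_distance <- function(a, b, normalize = TRUE) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  r <- .Call(C_dtw, a, b)
  if (normalize) r[1] / r[2] else r[1]
}

#' Overall window metrics
#'
#' @param z,x Equal-length numeric windows (estimate, reference).
#' @return A list: `mae`, `dtw` (path-normalized), `pcc` (Pearson; `NA` for a
#'   constant window).
#' @export
overall_metrics <- function(z, x) {
  if (length(z) != length(x))
    stop("windows must have equal length", call. = FALSE)
  pcc <- if (stats::sd(z) < 1e-12 || stats::sd(x) < 1e-12) NA_real_
         else stats::cor(z, x)
  list(mae = mean(abs(z - x)), dtw = dtw_distance(z, x), pcc = pcc)
}

#' Per-feature MAPE over matched cycles
#'
#' Cycles are matched 1:1 by onset order (the inputs come from synchronized
#' windows, so ordinal matching is exact). For each feature the MAPE
#' `100 * mean(|F_z - F_x| / |F_x|)` is taken over matched cycles where the
#' reference value is defined and nonzero; cycles where the estimate lacks
#' the feature are excluded from that feature's mean but reported in
#' `missing_rate`.
#'
#' @param z_cycles,x_cycles Lists of `cycle_fiducials` (equal length), e.g.
#'   from [stream_fiducials()].
#' @return A list: `mape` (named numeric, %), `missing_rate` (named numeric,
#'   fraction), `n_cycles`.
#' @export
feature_mape <- function(z_cycles, x_cycles) {
  n <- min(length(z_cycles), length(x_cycles))
  feats <- c("SP", "SW", "DW", "DN", "NT", "DP", "DT", "SA", "DA")
  if (n == 0L)
    return(list(mape = stats::setNames(rep(NA_real_, 9), feats),
                missing_rate = stats::setNames(rep(NA_real_, 9), feats),
                n_cycles = 0L))
  zf <- t(vapply(z_cycles[seq_len(n)], cycle_features, numeric(9)))
  xf <- t(vapply(x_cycles[seq_len(n)], cycle_features, numeric(9)))
  mape <- missing_rate <- stats::setNames(numeric(9), feats)
  for (f in feats) {
    ok_x <- !is.na(xf[, f]) & abs(xf[, f]) > 1e-12
    miss <- ok_x & is.na(zf[, f])
    use <- ok_x & !is.na(zf[, f])
    mape[f] <- if (any(use))
      100 * mean(abs(zf[use, f] - xf[use, f]) / abs(xf[use, f]))
      else NA_real_
    missing_rate[f] <- if (any(ok_x)) mean(miss[ok_x]) else NA_real_
  }
  list(mape = mape, missing_rate = missing_rate, n_cycles = n)
}

#' Skewness and kurtosis errors between two windows
#'
#' Skewness is the standardized third central moment; kurtosis is reported in
#' the non-excess (Pearson) convention, i.e. the standardized fourth central
#' moment with value 3 for a Gaussian (set `excess = TRUE` for the excess
#' convention — the absolute error is identical, the convention only matters
#' for reported per-window values).
#'
#' @param z,x Equal-length numeric windows.
#' @param excess Use excess kurtosis?
#' @return A list: `skew_mae`, `kurt_mae` (`NA` for zero-variance windows).
#' @export
sqi_errors <- function(z, x, excess = FALSE) {
  if (stats::sd(z) < 1e-12 || stats::sd(x) < 1e-12)
    return(list(skew_mae = NA_real_, kurt_mae = NA_real_))
  k0 <- if (excess) 0 else 3
  list(skew_mae = abs(e1071::skewness(z, type = 1) -
                      e1071::skewness(x, type = 1)),
       kurt_mae = abs((e1071::kurtosis(z, type = 1) + k0) -
                      (e1071::kurtosis(x, type = 1) + k0)))
}

# does the distorted/enhanced counterpart of a reference cycle carry a
# diastolic peak? cycle boundaries always come from the reference stream.
.has_dp <- function(seg, fs, prominence) {
  f <- tryCatch(detect_fiducials(seg, fs, prominence),
                error = function(e) NULL)
  !is.null(f) && !is.na(f$dp_idx)
}

#' Diastolic recovery rate
#'
#' Among reference cycles whose distorted counterpart lacks a diastolic peak,
#' the fraction whose enhanced counterpart has one. Cycle boundaries are the
#' reference onsets, so counterparts are sample-synchronized segments.
#'
#' @param z_windows,x_windows,d_windows Lists (or `T x N` matrices) of
#'   enhanced, reference and distorted windows.
#' @param fs Sampling rate (Hz).
#' @param prominence Peak-detection prominence.
#' @return A list: `rate` (`NA` if no cycle lacks a diastolic peak in the
#'   distorted input), `n_missing`, `n_recovered`.
#' @export
diastolic_recovery_rate <- function(z_windows, x_windows, d_windows, fs,
                                    prominence = 0.05) {
  as_list <- function(w) {
    if (is.list(w)) w else lapply(seq_len(ncol(as.matrix(w))),
                                  function(i) as.matrix(w)[, i])
  }
  zl <- as_list(z_windows); xl <- as_list(x_windows); dl <- as_list(d_windows)
  stopifnot(length(zl) == length(xl), length(xl) == length(dl))
  n_missing <- 0L
  n_recovered <- 0L
  for (i in seq_along(xl)) {
    v <- detect_valleys(xl[[i]], fs)
    if (length(v) < 2L) next
    for (k in seq_len(length(v) - 1L)) {
      rngk <- v[k]:v[k + 1L]
      if (!.has_dp(xl[[i]][rngk], fs, prominence)) next
      if (.has_dp(dl[[i]][rngk], fs, prominence)) next
      n_missing <- n_missing + 1L
      if (.has_dp(zl[[i]][rngk], fs, prominence))
        n_recovered <- n_recovered + 1L
    }
  }
  list(rate = if (n_missing == 0L) NA_real_ else n_recovered / n_missing,
       n_missing = n_missing, n_recovered = n_recovered)
}

#' Evaluate enhanced windows against references
#'
#' Aggregates the overall metrics (means over windows), the per-feature MAPE
#' (cycles pooled over windows, matched ordinally within each window), and
#' the SQI errors into one report.
#'
#' @param z_windows,x_windows Lists (or `T x N` matrices) of enhanced and
#'   reference windows.
#' @param fs Sampling rate (Hz).
#' @param prominence Peak-detection prominence.
#' @return An object of class `metrics_report`: `mae`, `dtw`, `pcc`, `mape`,
#'   `missing_rate`, `sqi_mae` (skewness/kurtosis), `n_windows`,
#'   `n_cycles_matched`, plus `per_window` (data.frame).
#' @export
evaluate_windows <- function(z_windows, x_windows, fs, prominence = 0.05) {
  zm <- if (is.list(z_windows)) sapply(z_windows, identity)
        else as.matrix(z_windows)
  xm <- if (is.list(x_windows)) sapply(x_windows, identity)
        else as.matrix(x_windows)
  stopifnot(ncol(zm) == ncol(xm))
  n <- ncol(zm)
  per <- data.frame(window = seq_len(n), mae = NA_real_, dtw = NA_real_,
                    pcc = NA_real_, skew_mae = NA_real_, kurt_mae = NA_real_)
  zc_all <- list()
  xc_all <- list()
  for (i in seq_len(n)) {
    om <- overall_metrics(zm[, i], xm[, i])
    sq <- sqi_errors(zm[, i], xm[, i])
    per$mae[i] <- om$mae; per$dtw[i] <- om$dtw; per$pcc[i] <- om$pcc
    per$skew_mae[i] <- sq$skew_mae; per$kurt_mae[i] <- sq$kurt_mae
    v <- detect_valleys(xm[, i], fs)
    if (length(v) >= 2L) {
      for (k in seq_len(length(v) - 1L)) {
        rngk <- v[k]:v[k + 1L]
        fx <- tryCatch(detect_fiducials(xm[rngk, i], fs, prominence),
                       error = function(e) NULL)
        fz <- tryCatch(detect_fiducials(zm[rngk, i], fs, prominence),
                       error = function(e) NULL)
        if (!is.null(fx) && !is.null(fz)) {
          xc_all[[length(xc_all) + 1L]] <- fx
          zc_all[[length(zc_all) + 1L]] <- fz
        }
      }
    }
  }
  fm <- feature_mape(zc_all, xc_all)
  structure(list(
    mae = mean(per$mae), dtw = mean(per$dtw),
    pcc = mean(per$pcc, na.rm = TRUE),
    mape = fm$mape, missing_rate = fm$missing_rate,
    sqi_mae = c(skewness = mean(per$skew_mae, na.rm = TRUE),
                kurtosis = mean(per$kurt_mae, na.rm = TRUE)),
    n_windows = n, n_cycles_matched = fm$n_cycles,
    per_window = per), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  overall: MAE %.4f  DTW %.4f  PCC %.4f  (%d windows)\n",
              x$mae, x$dtw, x$pcc, x$n_windows))
  cat("  MAPE (%):", paste(sprintf("%s %.2f", names(x$mape), x$mape),
                           collapse = "  "), "\n")
  cat(sprintf("  SQI MAE: skewness %.4f  kurtosis %.4f  (%d cycles matched)\n",
              x$sqi_mae[["skewness"]], x$sqi_mae[["kurtosis"]],
              x$n_cycles_matched))
  invisible(x)
}

#' Write a metrics report as JSON (plus optional per-window CSV)
#'
#' @param report A `metrics_report`.
#' @param path JSON output path.
#' @param csv_path Optional per-window CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path, csv_path = NULL) {
  stopifnot(inherits(report, "metrics_report"))
  out <- unclass(report)
  per <- out$per_window
  out$per_window <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) utils::write.csv(per, csv_path, row.names = FALSE)
  invisible(path)
}
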