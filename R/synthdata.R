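# Seeded synthetic paired PPG streams. A reference stream carries the ideal
# pulse morphology (systolic peak, dicrotic notch, diastolic peak at 30-90%
# of the systolic amplitude); a synchronized distorted companion emulates the
# effects of sub-optimal sensor contact pressure: suppressed notch/diastolic
# structure, systolic timing shift, slow amplitude modulation, baseline
# drift, and additive noise.

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Pulse template parameters
#'
#' Each cycle is the sum of two positive Gaussian bumps — systolic and
#' diastolic — plus a small negative Gaussian between them that deepens the
#' dicrotic notch. Positions and widths are fractions of the cycle length, so
#' the morphology is heart-rate invariant.
#'
#' @param fs Sampling rate (Hz).
#' @param hr_bpm Heart rate, 30-220 beats/min.
#' @param sys_amp Systolic amplitude (arbitrary units; everything downstream
#'   is min-max normalized, so 1 is a fine default).
#' @param sys_center_frac,sys_width_frac Center and Gaussian sigma of the
#'   systolic bump, as fractions of the cycle.
#' @param dia_amp_frac Diastolic amplitude as a fraction of the systolic
#'   amplitude; constrained to \[0.30, 0.90\] so generated references satisfy
#'   the morphological validity rule.
#' @param dia_center_frac,dia_width_frac Center and sigma of the diastolic
#'   bump (fractions of the cycle); must satisfy
#'   `0 < sys_center_frac < dia_center_frac < 1`.
#' @param notch_depth_frac Depth of the notch-deepening component as a
#'   fraction of the systolic amplitude (sigma 0.05 of the cycle, floored at
#'   two samples, centered midway between the two bumps).
#' @param hrv_jitter_ms Standard deviation of the Gaussian cycle-length
#'   jitter (ms); 0 gives perfectly periodic cycles.
#' @return An object of class `pulse_template`.
#' @export
pulse_template <- function(fs = 128, hr_bpm = 70, sys_amp = 1,
                           sys_center_frac = 0.26, sys_width_frac = 0.08,
                           dia_amp_frac = 0.55, dia_center_frac = 0.60,
                           dia_width_frac = 0.10, notch_depth_frac = 0.06,
                           hrv_jitter_ms = 10) {
  p <- list(fs = fs, hr_bpm = hr_bpm, sys_amp = sys_amp,
            sys_center_frac = sys_center_frac,
            sys_width_frac = sys_width_frac,
            dia_amp_frac = dia_amp_frac,
            dia_center_frac = dia_center_frac,
            dia_width_frac = dia_width_frac,
            notch_depth_frac = notch_depth_frac,
            hrv_jitter_ms = hrv_jitter_ms)
  if (fs <= 0) stop("fs must be > 0", call. = FALSE)
  if (hr_bpm < 30 || hr_bpm > 220)
    stop("hr_bpm must lie in [30, 220]", call. = FALSE)
  if (!(sys_center_frac > 0 && sys_center_frac < dia_center_frac &&
        dia_center_frac < 1))
    stop("need 0 < sys_center_frac < dia_center_frac < 1", call. = FALSE)
  if (dia_amp_frac < 0.30 || dia_amp_frac > 0.90)
    stop("dia_amp_frac must lie in [0.30, 0.90]", call. = FALSE)
  if (sys_width_frac <= 0 || dia_width_frac <= 0 || sys_amp <= 0 ||
      notch_depth_frac < 0 || hrv_jitter_ms < 0)
    stop("invalid pulse template parameter", call. = FALSE)
  p <- structure(p, class = "pulse_template")
  # numeric self-check: one canonical high-resolution cycle must carry the
  # ideal morphology (valid fiducials, minimum at the onset, not the notch)
  cyc <- template_cycle(p, 256L)
  f <- detect_fiducials(cyc, fs = 256)
  chk <- validate_cycle(f)
  if (!chk$valid)
    stop("template geometry does not produce a valid ideal cycle (",
         chk$reason, ")", call. = FALSE)
  if (which.min(cyc) > 16L && which.min(cyc) < 240L)
    stop("template geometry sinks below the onset level between the peaks",
         call. = FALSE)
  p
}

# evaluate one cycle of the template on n samples (phases 0..(n-1)/n)
template_cycle <- function(p, n) {
  u <- (seq_len(n) - 1) / n
  g <- function(c0, s0) exp(-(u - c0)^2 / (2 * s0^2))
  nc <- (p$sys_center_frac + p$dia_center_frac) / 2
  # the notch component is never narrower than ~2 samples, or coarse
  # sampling rates alias it into spurious wiggles
  nw <- max(0.05, 2 / n)
  y <- p$sys_amp * (g(p$sys_center_frac, p$sys_width_frac) +
                    p$dia_amp_frac * g(p$dia_center_frac, p$dia_width_frac) -
                    p$notch_depth_frac * g(nc, nw))
  y
}

#' Synthesize a reference PPG stream with ideal morphology
#'
#' Generates contiguous cycles of the pulse template; cycle lengths follow
#' `60/hr_bpm` seconds plus seeded Gaussian jitter. The returned signal
#' carries a `truth` attribute: a data.frame of per-cycle ground-truth sample
#' indices (1-based `onset`, `sp`, `dn`, `dp`, `next_onset`) derived from the
#' template component centers.
#'
#' @param params A [pulse_template()].
#' @param duration_s Duration in seconds (at least two cycles).
#' @param seed Integer RNG seed (only the cycle jitter is random).
#' @return A [ppg_signal()] with attribute `truth`.
#' @export
synthesize_reference <- function(params, duration_s, seed = 1L) {
  stopifnot(inherits(params, "pulse_template"))
  if (duration_s < 2 * 60 / params$hr_bpm)
    stop("duration_s must span at least 2 cycles", call. = FALSE)
  fs <- params$fs
  n_total <- round(duration_s * fs)
  period <- 60 / params$hr_bpm

  with_seed(seed, {
    # continuous-time onsets, then snapped to the sample grid
    t_on <- 0
    repeat {
      jit <- if (params$hrv_jitter_ms > 0)
        stats::rnorm(1, 0, params$hrv_jitter_ms / 1000) else 0
      nxt <- t_on[length(t_on)] + max(0.4 * period, period + jit)
      t_on <- c(t_on, nxt)
      if (nxt * fs >= n_total) break
    }
    b <- round(t_on * fs) # 0-based boundary samples
    x <- numeric(b[length(b)])
    truth <- vector("list", length(b) - 1L)
    nc <- (params$sys_center_frac + params$dia_center_frac) / 2
    for (k in seq_len(length(b) - 1L)) {
      nk <- b[k + 1L] - b[k]
      x[(b[k] + 1L):b[k + 1L]] <- template_cycle(params, nk)
      truth[[k]] <- data.frame(
        onset = b[k] + 1L,
        sp = b[k] + 1L + round(params$sys_center_frac * nk),
        dn = b[k] + 1L + round(nc * nk),
        dp = b[k] + 1L + round(params$dia_center_frac * nk),
        next_onset = b[k + 1L] + 1L)
    }
    truth <- do.call(rbind, truth)
    # drop cycles truncated by the requested duration; the final cycle's
    # next_onset is clamped into the signal
    truth <- truth[truth$next_onset <= n_total + 1L, , drop = FALSE]
    truth$next_onset <- pmin(truth$next_onset, n_total)
    sig <- ppg_signal(x[seq_len(min(length(x), n_total))], fs = fs)
    attr(sig, "truth") <- truth
    sig
  })
}

#' Contact-pressure distortion parameters
#'
#' @param notch_suppress Factor in \[0, 1\] blending the signal toward a
#'   smoothed copy that lacks the notch/diastolic structure (0 = none,
#'   1 = fully suppressed).
#' @param peak_shift_ms Temporal shift of the whole pulse train (ms);
#'   implemented as a fractional delay with edge replication.
#' @param amp_mod_depth Depth of a slow (0.2 Hz) multiplicative amplitude
#'   modulation.
#' @param drift_amp,drift_freq_hz Additive sinusoidal baseline drift
#'   amplitude and frequency.
#' @param noise_sd Additive white Gaussian noise SD.
#' @param seed Integer RNG seed; identical seeds give bit-identical output.
#' @return An object of class `distortion_params`.
#' @export
distortion_params <- function(notch_suppress = 0.8, peak_shift_ms = 30,
                              amp_mod_depth = 0.2, drift_amp = 0.2,
                              drift_freq_hz = 0.15, noise_sd = 0.01,
                              seed = 1L) {
  d <- list(notch_suppress = notch_suppress, peak_shift_ms = peak_shift_ms,
            amp_mod_depth = amp_mod_depth, drift_amp = drift_amp,
            drift_freq_hz = drift_freq_hz, noise_sd = noise_sd,
            seed = as.integer(seed))
  if (notch_suppress < 0 || notch_suppress > 1)
    stop("notch_suppress must lie in [0, 1]", call. = FALSE)
  if (peak_shift_ms < 0 || amp_mod_depth < 0 || drift_amp < 0 ||
      drift_freq_hz < 0 || noise_sd < 0)
    stop("distortion magnitudes must be >= 0", call. = FALSE)
  structure(d, class = "distortion_params")
}

# Gaussian smoothing with edge replication; sigma in samples
gauss_smooth <- function(x, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + length(x))]
}

#' Apply contact-pressure distortions to a reference stream
#'
#' Distortions are composed in a fixed, documented order: notch suppression,
#' peak shift, amplitude modulation, baseline drift, noise. With all
#' magnitudes zero the output equals the input sample-for-sample.
#'
#' @param reference A [ppg_signal()], normally from [synthesize_reference()].
#' @param d A [distortion_params()].
#' @return A [ppg_signal()] of the same length and sampling rate.
#' @export
distort_signal <- function(reference, d) {
  stopifnot(inherits(reference, "ppg_signal"),
            inherits(d, "distortion_params"))
  x <- reference$samples
  fs <- reference$fs
  tt <- (seq_along(x) - 1) / fs
  with_seed(d$seed, {
    y <- x
    if (d$notch_suppress > 0) {
      sm <- gauss_smooth(y, sigma = 0.12 * fs)
      y <- (1 - d$notch_suppress) * y + d$notch_suppress * sm
    }
    if (d$peak_shift_ms > 0) {
      shift <- d$peak_shift_ms / 1000
      y <- stats::approx(tt, y, xout = tt - shift, rule = 2)$y
    }
    if (d$amp_mod_depth > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      y <- y * (1 + d$amp_mod_depth * sin(2 * pi * 0.2 * tt + phase))
    }
    if (d$drift_amp > 0 && d$drift_freq_hz > 0) {
      phase2 <- stats::runif(1, 0, 2 * pi)
      y <- y + d$drift_amp * sin(2 * pi * d$drift_freq_hz * tt + phase2)
    }
    if (d$noise_sd > 0) y <- y + stats::rnorm(length(y), 0, d$noise_sd)
    ppg_signal(y, fs = fs, t0 = reference$t0)
  })
}

#' Default subject parameter ranges for the synthetic study
#'
#' Per-subject template and distortion parameters are drawn uniformly from
#' these ranges and held fixed within a subject, emulating inter-subject
#' variability with within-subject stability.
#'
#' @return A named list of `c(min, max)` ranges.
#' @export
template_ranges <- function() {
  list(hr_bpm = c(55, 90),
       sys_center_frac = c(0.24, 0.28),
       sys_width_frac = c(0.08, 0.09),
       dia_amp_frac = c(0.45, 0.65),
       dia_center_frac = c(0.58, 0.62),
       dia_width_frac = c(0.10, 0.12),
       notch_depth_frac = c(0.04, 0.07),
       hrv_jitter_ms = c(5, 20))
}

#' @rdname template_ranges
#' @export
distortion_ranges <- function() {
  list(notch_suppress = c(0.5, 0.95),
       peak_shift_ms = c(0, 50),
       amp_mod_depth = c(0, 0.3),
       drift_amp = c(0, 0.3),
       drift_freq_hz = c(0.05, 0.3),
       noise_sd = c(0.005, 0.02))
}

draw_range <- function(rng) stats::runif(1, rng[1], rng[2])

#' Build a paired synthetic dataset with subject-disjoint splits
#'
#' Draws per-subject template and distortion parameters, synthesizes paired
#' streams, runs the preprocessing pipeline (lowpass + DC removal, optional
#' invalid-segment removal on the reference, windowing, normalization) and
#' assigns whole subjects to train/validation/test.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param minutes_per_subject Minutes of signal per subject.
#' @param tranges,dranges Parameter ranges, as [template_ranges()] /
#'   [distortion_ranges()].
#' @param fs Sampling rate (Hz).
#' @param win_s,stride_s Window length and stride (s).
#' @param split Relative train/validation/test proportions (subjects);
#'   default 13/4/5.
#' @param validity_filter Remove reference cycles failing the morphology rule
#'   (and their synchronized distorted counterparts) before windowing.
#' @param lowpass Apply the lowpass/DC-removal stage.
#' @param seed Integer RNG seed; the full dataset is reproducible from it.
#' @return A list of class `ppg_dataset`: `pairs` (list of [window_pair()]),
#'   `split` (list of index vectors `train`, `val`, `test`), `manifest`
#'   (per-subject parameter data.frame), `fs`, `win_s`, `stride_s`, `seed`.
#' @export
make_dataset <- function(n_subjects, minutes_per_subject,
                         tranges = template_ranges(),
                         dranges = distortion_ranges(),
                         fs = 128, win_s = 8, stride_s = 1.6,
                         split = c(train = 13, val = 4, test = 5),
                         validity_filter = TRUE, lowpass = TRUE,
                         seed = 1L) {
  stopifnot(n_subjects >= 1, minutes_per_subject > 0)
  subj_seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2,
                                           n_subjects * 2))
  pairs <- list()
  manifest <- list()
  subject_of_pair <- integer(0)

  for (s in seq_len(n_subjects)) {
    tp_draw <- with_seed(subj_seeds[2 * s - 1], lapply(tranges, draw_range))
    dp_draw <- with_seed(subj_seeds[2 * s], lapply(dranges, draw_range))
    tp <- do.call(pulse_template, c(list(fs = fs), tp_draw))
    dp <- do.call(distortion_params,
                  c(dp_draw, list(seed = subj_seeds[2 * s])))
    ref <- synthesize_reference(tp, duration_s = minutes_per_subject * 60,
                                seed = subj_seeds[2 * s - 1])
    dis <- distort_signal(ref, dp)
    if (lowpass) {
      ref <- lowpass_dc_remove(ref)
      dis <- lowpass_dc_remove(dis)
    }
    if (validity_filter) {
      frags <- remove_invalid_segments(ref, dis)$fragments
    } else {
      frags <- list(list(reference = ref, distorted = dis, offset = 0L))
    }
    for (fr in frags) {
      ws <- window_pairs(fr$reference, fr$distorted,
                         win_s = win_s, stride_s = stride_s)
      ws <- normalize_pairs(ws)
      for (w in ws) {
        w$subject <- sprintf("S%02d", s)
        w$source_offset <- w$source_offset + fr$offset
        pairs[[length(pairs) + 1L]] <- w
        subject_of_pair <- c(subject_of_pair, s)
      }
    }
    manifest[[s]] <- data.frame(subject = sprintf("S%02d", s),
                                as.data.frame(tp_draw),
                                as.data.frame(dp_draw))
  }
  manifest <- do.call(rbind, manifest)

  # subject-disjoint split
  split <- split / sum(split)
  n_tr <- max(1L, round(split[[1]] * n_subjects))
  n_va <- max(if (n_subjects >= 3) 1L else 0L, round(split[[2]] * n_subjects))
  while (n_tr + n_va >= n_subjects && n_tr > 1L) n_tr <- n_tr - 1L
  order_s <- with_seed(seed + 1L, sample.int(n_subjects))
  assign <- rep("test", n_subjects)
  assign[order_s[seq_len(n_tr)]] <- "train"
  if (n_va > 0 && n_tr + n_va <= n_subjects)
    assign[order_s[n_tr + seq_len(n_va)]] <- "val"
  manifest$split <- assign

  idx <- list(train = which(subject_of_pair %in% which(assign == "train")),
              val = which(subject_of_pair %in% which(assign == "val")),
              test = which(subject_of_pair %in% which(assign == "test")))

  structure(list(pairs = pairs, split = idx, manifest = manifest, fs = fs,
                 win_s = win_s, stride_s = stride_s, seed = seed),
            class = "ppg_dataset")
}

#' @export
print.ppg_dataset <- function(x, ...) {
  cat(sprintf(
    "<ppg_dataset> %d window pairs (%d train / %d val / %d test), %d subjects @ %g Hz\n",
    length(x$pairs), length(x$split$train), length(x$split$val),
    length(x$split$test), nrow(x$manifest), x$fs))
  invisible(x)
}

#' Write a dataset as CSV signals plus a JSON manifest
#'
#' Each window pair is written as one CSV with columns `time_s`,
#' `distorted`, `reference`; subjects, parameters, seeds and split
#' assignments go into `manifest.json`.
#'
#' @param ds A `ppg_dataset` from [make_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "ppg_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(ds$pairs))
  for (i in seq_along(ds$pairs)) {
    w <- ds$pairs[[i]]
    files[i] <- sprintf("pair_%05d.csv", i)
    utils::write.csv(
      data.frame(time_s = (seq_along(w$reference) - 1) / w$fs,
                 distorted = w$distorted, reference = w$reference),
      file.path(dir, files[i]), row.names = FALSE)
  }
  manifest <- list(fs = ds$fs, win_s = ds$win_s, stride_s = ds$stride_s,
                   seed = ds$seed, subjects = ds$manifest,
                   split = ds$split,
                   files = files,
                   subject_of_pair = vapply(ds$pairs, `[[`, character(1),
                                            "subject"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
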