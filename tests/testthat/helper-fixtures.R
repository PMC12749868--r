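# Shared fixtures, built in code at test time.

# a clean reference stream: 70 bpm at 128 Hz unless overridden
ref_stream <- function(duration_s = 10, hr = 70, fs = 128, jitter = 0,
                       dia = 0.55, seed = 1) {
  synthesize_reference(
    pulse_template(fs = fs, hr_bpm = hr, dia_amp_frac = dia,
                   hrv_jitter_ms = jitter),
    duration_s = duration_s, seed = seed)
}

# zero-magnitude distortion (identity)
identity_distortion <- function() {
  distortion_params(notch_suppress = 0, peak_shift_ms = 0, amp_mod_depth = 0,
                    drift_amp = 0, drift_freq_hz = 0, noise_sd = 0, seed = 1)
}

# a hand-constructed stream of cycles with per-cycle dia amplitude and an
# optional extra bump, for validity-filter fixtures. Returns the signal plus
# the intended per-cycle validity labels.
cycle_fixture <- function(dia_fracs, extra_bump = rep(FALSE, length(dia_fracs)),
                          drop_dia = rep(FALSE, length(dia_fracs)),
                          fs = 128, n = 128) {
  u <- (seq_len(n) - 1) / n
  g <- function(c0, s0) exp(-(u - c0)^2 / (2 * s0^2))
  cycles <- lapply(seq_along(dia_fracs), function(k) {
    dia <- if (drop_dia[k]) 0 else dia_fracs[k]
    notch <- if (drop_dia[k]) 0 else 0.08
    if (dia > 0.9) {
      # near-systolic diastolic wave: physiologically the notch is shallow,
      # and a shallow saddle keeps onset detection unambiguous
      y <- g(0.26, 0.10) + dia * g(0.60, 0.14)
    } else {
      y <- g(0.26, 0.08) + dia * g(0.60, 0.10) - notch * g(0.43, 0.05)
    }
    if (extra_bump[k]) y <- y + 0.35 * g(0.82, 0.04)
    y
  })
  ppg_signal(unlist(cycles), fs = fs)
}

# tiny architecture used wherever a full-size model is unnecessary
tiny_config <- function() {
  generator_config(depth = 2L, channels = c(4L, 6L), lstm_hidden = 5L,
                   gn_groups = 2L)
}

# scaled-down training architecture (shared by the training tests)
small_config <- function() {
  generator_config(depth = 2L, channels = c(8L, 16L), lstm_hidden = 16L,
                   gn_groups = 4L)
}

expect_equal_num <- function(a, b, tol = 1e-9) {
  expect_true(all(abs(a - b) < tol))
}
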