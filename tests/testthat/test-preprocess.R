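test_that("DC removal annihilates a constant signal", {
  s <- ppg_signal(rep(3.7, 512), fs = 128)
  out <- lowpass_dc_remove(s)
  expect_lt(max(abs(out$samples)), 1e-9)
})

test_that("filter attenuates 30 Hz by > 40 dB and passes 1 Hz within 5%", {
  fs <- 128
  t <- (0:(fs * 16 - 1)) / fs
  s <- ppg_signal(sin(2 * pi * 1 * t) + sin(2 * pi * 30 * t), fs = fs)
  out <- lowpass_dc_remove(s)
  # FFT amplitude at the two tones (integer periods over the record)
  amp <- function(x, f) {
    n <- length(x)
    2 * abs(stats::fft(x)[f * n / fs + 1]) / n
  }
  expect_lt(amp(out$samples, 30) / amp(s$samples, 30), 10^(-40 / 20))
  expect_lt(abs(amp(out$samples, 1) - 1), 0.05)
})

test_that("a slow zero-mean sinusoid passes essentially unchanged", {
  fs <- 128
  t <- (0:(fs * 8 - 1)) / fs
  x <- sin(2 * pi * 0.5 * t)          # 4 integer periods, zero mean
  out <- lowpass_dc_remove(ppg_signal(x, fs = fs))
  expect_lt(max(abs(out$samples - x)), 0.02 * max(abs(x)))
})

test_that("filtering requires an adequate sampling rate", {
  expect_error(lowpass_dc_remove(ppg_signal(rnorm(64), fs = 16)), "too low")
})

test_that("invalid cycles and their synchronized counterparts are removed", {
  # 10 cycles, cycles 4 and 8 with diastolic amplitude 0.95 of max
  dia <- rep(0.55, 10)
  dia[c(4, 8)] <- 0.95
  ref <- cycle_fixture(dia)
  dist <- ppg_signal(ref$samples * 0.9 + 0.01, fs = ref$fs)  # any synchronized copy
  seg <- remove_invalid_segments(ref, dist)
  expect_equal(sum(seg$kept), 8)
  expect_equal(which(!seg$kept), c(4, 8))
  expect_true(all(grepl("diastolic too large", seg$reasons[c(4, 8)])))
  # fragments cover exactly the valid runs, both channels in sync
  for (fr in seg$fragments) {
    expect_length(fr$reference$samples, length(fr$distorted$samples))
    expect_equal(fr$distorted$samples, fr$reference$samples * 0.9 + 0.01,
                 tolerance = 1e-12)
  }
})

test_that("a cycle with an extraneous peak is rejected", {
  ref <- cycle_fixture(rep(0.55, 5), extra_bump = c(F, F, T, F, F))
  seg <- remove_invalid_segments(ref, ref)
  expect_false(seg$kept[3])
  expect_match(seg$reasons[3], "extraneous")
  expect_equal(sum(seg$kept), 4)
})

test_that("an all-valid stream keeps every cycle", {
  ref <- cycle_fixture(rep(0.5, 6))
  seg <- remove_invalid_segments(ref, ref)
  expect_true(all(seg$kept))
  expect_length(seg$fragments, 1)
})

test_that("window counts follow floor((L - W)/S) + 1 exactly", {
  fs <- 128
  cases <- list(c(1024, 8, 1.6), c(2048, 8, 1.6), c(1024, 8, 8),
                c(3000, 8, 1.6), c(1500, 4, 1), c(4096, 8, 1.6),
                c(1025, 8, 1.6), c(2047, 8, 1.6), c(1200, 5, 2),
                c(5000, 10, 3))
  for (cs in cases) {
    L <- cs[1]
    W <- round(cs[2] * fs)
    S <- round(cs[3] * fs)
    sig <- ppg_signal(sin(seq_len(L) / 10), fs = fs)
    ws <- window_pairs(sig, sig, win_s = cs[2], stride_s = cs[3])
    expect_length(ws, floor((L - W) / S) + 1)
    offs <- vapply(ws, `[[`, integer(1), "source_offset")
    expect_equal(offs, seq(0L, by = S, length.out = length(ws)))
  }
})

test_that("windows shorter than the fragment are skipped with a message", {
  sig <- ppg_signal(sin(1:100), fs = 128)
  expect_message(ws <- window_pairs(sig, sig, win_s = 8), "skipped")
  expect_length(ws, 0)
})

test_that("adjacent windows overlap by W - S samples", {
  sig <- ppg_signal(sin(seq_len(2048) / 7), fs = 128)
  ws <- window_pairs(sig, sig, 8, 1.6)
  W <- 1024
  S <- round(1.6 * 128)
  a <- ws[[1]]$reference
  b <- ws[[2]]$reference
  expect_identical(a[(S + 1):W], b[1:(W - S)])
})

test_that("normalization maps to [0,1], is idempotent and affine-invariant", {
  w <- window_pair(c(2, 4, 6), c(1, 2, 4), fs = 128)
  nw <- normalize_pair(w)
  expect_equal(nw$distorted, c(0, 0.5, 1))
  expect_identical(normalize_pair(nw)$distorted, nw$distorted) # idempotent
  w2 <- window_pair(5 * c(2, 4, 6) - 3, 2 * c(1, 2, 4) + 1, fs = 128)
  nw2 <- normalize_pair(w2)
  expect_equal(nw2$distorted, nw$distorted, tolerance = 1e-12)
  expect_equal(nw2$reference, nw$reference, tolerance = 1e-12)
  # order statistics preserved
  expect_identical(order(nw$reference), order(w$reference))
})

test_that("constant windows raise a degenerate-window error and are dropped", {
  w <- window_pair(rep(1, 10), 1:10, fs = 128)
  expect_error(normalize_pair(w), class = "ppg_degenerate_window")
  good <- window_pair(1:10, 1:10, fs = 128)
  expect_message(out <- normalize_pairs(list(w, good)), "dropped")
  expect_length(out, 1)
})

test_that("augmentation with zero magnitudes is the identity and counts multiply", {
  ds <- make_dataset(1, 0.6, fs = 64, seed = 2, split = c(1, 0, 0))
  pairs <- ds$pairs[1:5]
  zero <- list(time_warp = 0, jitter = 0, baseline_drift = 0, amp_scale = 0)
  out <- augment_pairs(pairs, ops = zero, multiplier = 1, seed = 1)
  expect_length(out, 5)
  for (i in 1:5) {
    expect_identical(out[[i]]$reference, pairs[[i]]$reference)
    expect_identical(out[[i]]$distorted, pairs[[i]]$distorted)
  }
  out3 <- augment_pairs(pairs, multiplier = 3, seed = 1)
  expect_length(out3, 15)
  out3b <- augment_pairs(pairs, multiplier = 3, seed = 1)
  expect_identical(out3[[7]]$reference, out3b[[7]]$reference) # seeded
})

test_that("small jitter stays within 5 SD for almost all samples", {
  ds <- make_dataset(1, 0.6, fs = 64, seed = 4, split = c(1, 0, 0))
  pairs <- ds$pairs[1:4]
  out <- augment_pairs(pairs, ops = list(jitter = 0.01), multiplier = 1,
                       seed = 2)
  devs <- unlist(lapply(seq_along(pairs), function(i)
    abs(out[[i]]$reference - pairs[[i]]$reference)))
  expect_gte(mean(devs <= 5 * 0.01), 0.99)
})

test_that("the pipeline preserves pair synchronization on (x, x)", {
  s <- ref_stream(duration_s = 20, jitter = 5, seed = 6)
  ws <- suppressMessages(preprocess_pair(s, s))
  expect_gt(length(ws), 0)
  for (w in ws) expect_identical(w$reference, w$distorted)
})

test_that("signal CSV round-trips", {
  s <- ref_stream(duration_s = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ppg_csv(s, path)
  s2 <- read_ppg_csv(path)
  expect_equal(s2$fs, s$fs, tolerance = 1e-9)
  expect_equal(s2$samples, s$samples, tolerance = 1e-12)
})
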