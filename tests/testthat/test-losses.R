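# Straight-line reimplementations used as oracles. They share nothing with
# the package internals beyond the peak detector's public contract.
oracle_hinge <- function(sr, sf) {
  tot <- 0
  for (i in seq_along(sr))
    tot <- tot + max(0, 1 - sr[i]) + max(0, 1 + sf[i])
  tot / length(sr)
}

oracle_mse <- function(z, x) {
  s <- 0
  for (i in seq_along(z)) s <- s + (z[i] - x[i])^2
  s / length(z)
}

test_that("hinge loss matches hand cases and the oracle on random inputs", {
  expect_identical(hinge_d_loss(rep(1, 4), rep(-1, 4)), 0)  # margins met
  expect_identical(hinge_d_loss(0, 0), 2)
  expect_equal(hinge_d_loss(-0.5, 0.3), 1.5 + 1.3, tolerance = 1e-12)
  set.seed(21)
  for (i in 1:50) {
    n <- sample(1:8, 1)
    sr <- rnorm(n)
    sf <- rnorm(n)
    expect_equal(hinge_d_loss(sr, sf), oracle_hinge(sr, sf),
                 tolerance = 1e-9)
  }
  expect_error(hinge_d_loss(numeric(0), numeric(0)), "non-empty")
  expect_error(hinge_d_loss(1:3, 1:2), "equal length")
})

test_that("count_peaks handles canonical shapes", {
  expect_equal(count_peaks(c(0, 0.5, 1, 0.5, 0)), 1)   # triangular pulse
  expect_equal(count_peaks(rep(0.3, 100)), 0)          # flat
  s <- ref_stream(duration_s = 8, hr = 60, jitter = 0)
  w <- (s$samples - min(s$samples)) / diff(range(s$samples))
  expect_equal(count_peaks(w), 16)                     # 2 peaks x 8 cycles
})

test_that("custom loss switches regimes on the peak-count difference", {
  s <- ref_stream(duration_s = 8, hr = 60, jitter = 0)
  x <- (s$samples - min(s$samples)) / diff(range(s$samples))
  # identity: matched regime, exact zero
  cl <- custom_loss(x, x, fs = 128)
  expect_equal(cl$regime, "point")
  expect_identical(cl$value, 0)
  # flat estimate vs 2-peak reference: alpha = 2, value = 3 * MSE
  x2 <- c(rep(0, 20), 0.2, 0.6, 1, 0.6, 0.2, rep(0, 20), 0.1, 0.4,
          0.8, 0.4, 0.1, rep(0, 18))
  z <- rep(0.25, length(x2))
  m <- oracle_mse(z, x2)
  cl2 <- custom_loss(z, x2, fs = 128)
  expect_equal(cl2$alpha, 2)
  expect_equal(cl2$regime, "peak_count")
  expect_equal(cl2$value, 3 * m, tolerance = 1e-9)
})

test_that("peak-count regime equals (1 + alpha) * MSE against the oracle", {
  set.seed(33)
  for (i in 1:50) {
    # 32-sample pair with a controlled peak-count difference
    x <- rep(0, 32)
    x[8] <- 1; x[20] <- 0.6            # two triangular-ish peaks
    x[7] <- x[9] <- 0.4; x[19] <- x[21] <- 0.3
    z <- pmax(0, x + rnorm(32, 0, 0.02))
    z[20] <- 0                          # typically kills the second peak
    cl <- custom_loss(z, x, fs = 128)
    if (cl$regime == "peak_count") {
      expect_equal(cl$value, (1 + cl$alpha) * oracle_mse(z, x),
                   tolerance = 1e-9)
    }
  }
})

test_that("p2p loss matches hand constructions", {
  s <- ref_stream(duration_s = 8, hr = 60, jitter = 0)
  x <- (s$samples - min(s$samples)) / diff(range(s$samples))
  expect_identical(p2p_loss(x, x, fs = 128), 0)
  # uniform +0.1 amplitude offset, fiducials unmoved: 0.3 per cycle
  z <- x + 0.1
  expect_equal(p2p_loss(z, x, fs = 128), 0.3, tolerance = 1e-9)
  # estimate missing the diastolic peak in all cycles: >= 1.0 per cycle
  d <- distort_signal(s, distortion_params(
    notch_suppress = 1, peak_shift_ms = 0, amp_mod_depth = 0, drift_amp = 0,
    noise_sd = 0))
  zd <- (d$samples - min(d$samples)) / diff(range(d$samples))
  expect_gte(p2p_loss(zd, x, fs = 128), 1.0)
  expect_error(p2p_loss(rep(0.5, 64), rep(0.5, 64), fs = 128), "cycles")
})

test_that("generator loss combines custom and adversarial terms", {
  s <- ref_stream(duration_s = 8, hr = 60, jitter = 0)
  x <- (s$samples - min(s$samples)) / diff(range(s$samples))
  xb <- cbind(x, x, x)
  # theta = 0: mean custom loss exactly
  gl0 <- generator_loss(xb, xb, d_scores_fake = c(5, -5, 0), fs = 128,
                        cfg = loss_config(theta = 0))
  expect_identical(gl0$value, 0)
  # L_C = 0, D(z) = c: value is -theta * c
  glc <- generator_loss(xb, xb, d_scores_fake = c(2, 2, 2), fs = 128,
                        cfg = loss_config(theta = 0.01))
  expect_equal(glc$value, -0.01 * 2, tolerance = 1e-12)
  expect_error(generator_loss(xb[, 0], xb[, 0], numeric(0), 128), "empty")
})

test_that("generator loss matches a straight-line oracle on random batches", {
  set.seed(44)
  s <- ref_stream(duration_s = 8, hr = 70, jitter = 0)
  x <- (s$samples - min(s$samples)) / diff(range(s$samples))
  cfg <- loss_config()
  for (rep in 1:10) {
    n <- 3
    zb <- vapply(1:n, function(i) pmin(1, pmax(0, x + rnorm(length(x), 0, 0.05))),
                 numeric(length(x)))
    xb <- matrix(x, length(x), n)
    d <- rnorm(n)
    gl <- generator_loss(zb, xb, d, fs = 128, cfg = cfg)
    # oracle: per-window custom loss from public primitives
    vals <- numeric(n)
    for (i in 1:n) {
      a <- abs(count_peaks(zb[, i]) - count_peaks(xb[, i]))
      m <- oracle_mse(zb[, i], xb[, i])
      vals[i] <- if (a != 0) m * (1 + a)
                 else p2p_loss(zb[, i], xb[, i], 128) * cfg$beta + m
    }
    expect_equal(gl$value, mean(vals) - cfg$theta * mean(d),
                 tolerance = 1e-9)
  }
})

test_that("loss gradients match finite differences", {
  s <- ref_stream(duration_s = 4, hr = 60, jitter = 0)
  x <- (s$samples - min(s$samples)) / diff(range(s$samples))
  set.seed(55)
  cfg <- loss_config()
  for (scenario in c("matched", "mismatched")) {
    z <- if (scenario == "matched") pmin(1, pmax(0, x + rnorm(length(x), 0, 0.01)))
         else rep(0.4, length(x)) + rnorm(length(x), 0, 0.001)
    cg <- ppgrestore:::custom_loss_grad(z, x, 128, cfg)
    eps <- 1e-6
    for (j in sample(seq_along(z), 5)) {
      # skip points that sit exactly on a detected fiducial: the regime/
      # fiducial assignment is piecewise constant but can flip under eps
      zp <- z; zp[j] <- zp[j] + eps
      zm <- z; zm[j] <- zm[j] - eps
      vp <- ppgrestore:::custom_loss_grad(zp, x, 128, cfg)
      vm <- ppgrestore:::custom_loss_grad(zm, x, 128, cfg)
      if (vp$regime == cg$regime && vm$regime == cg$regime &&
          identical(vp$alpha, cg$alpha) && identical(vm$alpha, cg$alpha)) {
        num <- (vp$value - vm$value) / (2 * eps)
        expect_equal(cg$grad[j], num, tolerance = 1e-3)
      }
    }
  }
})
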