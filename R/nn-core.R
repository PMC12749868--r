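# Minimal neural-network layer kit used by the generator and discriminator.
#
# Tensors are dense arrays of dim c(channels, time, batch). Every layer is a
# pair of functions: *_fwd(params, x) returning list(y, cache) and
# *_bwd(params, cache, gy) returning list(gx, g) with `g` shaped like
# `params`. Convolutions are realized as one BLAS matmul on an im2col matrix;
# the only sequential computation is the LSTM time loop. There is no
# framework underneath: the backward passes are written out by hand and are
# checked against finite differences in the test suite.

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

as_ctb <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  if (is.matrix(x)) return(array(x, c(1L, nrow(x), ncol(x))))
  array(as.numeric(x), c(1L, length(x), 1L))
}

# ---- 1D convolution (kernel k, stride 1, zero padding (k-1)/2) -------------

conv_init <- function(cin, cout, k = 3L) {
  sd <- sqrt(2 / (cin * k))
  list(W = matrix(stats::rnorm(cout * cin * k, 0, sd), cout, cin * k),
       b = numeric(cout), k = k)
}

im2col <- function(x, k) {
  d <- dim(x)
  C <- d[1]; Tt <- d[2]; B <- d[3]
  p <- (k - 1L) %/% 2L
  xp <- array(0, c(C, Tt + 2L * p, B))
  xp[, (p + 1L):(p + Tt), ] <- x
  blocks <- vector("list", k)
  for (j in seq_len(k)) {
    s <- xp[, j:(j + Tt - 1L), , drop = FALSE]
    dim(s) <- c(C, Tt * B)
    blocks[[j]] <- s
  }
  do.call(rbind, blocks)
}

conv_fwd <- function(p, x) {
  d <- dim(x)
  K <- im2col(x, p$k)
  y <- p$W %*% K + p$b
  dim(y) <- c(nrow(p$W), d[2], d[3])
  list(y = y, cache = list(x = x))
}

conv_bwd <- function(p, cache, gy) {
  x <- cache$x
  d <- dim(x)
  C <- d[1]; Tt <- d[2]; B <- d[3]
  k <- p$k
  pd <- (k - 1L) %/% 2L
  K <- im2col(x, k)
  gym <- gy
  dim(gym) <- c(dim(gy)[1], Tt * B)
  gW <- tcrossprod(gym, K)
  gb <- rowSums(gym)
  gK <- crossprod(p$W, gym)
  gxp <- array(0, c(C, Tt + 2L * pd, B))
  for (j in seq_len(k)) {
    blk <- gK[((j - 1L) * C + 1L):(j * C), , drop = FALSE]
    dim(blk) <- c(C, Tt, B)
    gxp[, j:(j + Tt - 1L), ] <- gxp[, j:(j + Tt - 1L), , drop = FALSE] + blk
  }
  gx <- gxp[, (pd + 1L):(pd + Tt), , drop = FALSE]
  list(gx = gx, g = list(W = gW, b = gb, k = 0))
}

# ---- gated convolution: conv_a(x) * sigmoid(conv_b(x)) ---------------------

gated_conv_init <- function(cin, cout, k = 3L) {
  list(a = conv_init(cin, cout, k), b = conv_init(cin, cout, k))
}

#' Gated 1D convolution
#'
#' Computes `conv_a(x) * sigmoid(conv_b(x))` elementwise over channels and
#' time: a learned sigmoid gate modulates the information flow of the main
#' convolution branch.
#'
#' @param p Parameters from the internal initializer (two convolution
#'   branches `a` and `b`, each with weight matrix `W`, bias `b`, kernel `k`).
#' @param x Input array of dim `c(channels, time, batch)`.
#' @return A list with the output array `y` (and a `cache` for the backward
#'   pass).
#' @keywords internal
#' @export
gated_conv_fwd <- function(p, x) {
  fa <- conv_fwd(p$a, x)
  fb <- conv_fwd(p$b, x)
  s <- nn_sigmoid(fb$y)
  list(y = fa$y * s,
       cache = list(ca = fa$cache, cb = fb$cache, ya = fa$y, s = s))
}

gated_conv_bwd <- function(p, cache, gy) {
  gya <- gy * cache$s
  gyb <- gy * cache$ya * cache$s * (1 - cache$s)
  ba <- conv_bwd(p$a, cache$ca, gya)
  bb <- conv_bwd(p$b, cache$cb, gyb)
  list(gx = ba$gx + bb$gx, g = list(a = ba$g, b = bb$g))
}

# ---- GroupNorm -------------------------------------------------------------

groupnorm_init <- function(C, groups = 8L) {
  list(gamma = rep(1, C), beta = numeric(C),
       groups = as.integer(min(groups, C)))
}

groupnorm_fwd <- function(p, x, eps = 1e-5) {
  d <- dim(x)
  C <- d[1]; Tt <- d[2]; B <- d[3]
  G <- p$groups
  Cg <- C %/% G
  stopifnot(Cg * G == C)
  xhat <- array(0, d)
  inv <- matrix(0, G, B)
  for (g in seq_len(G)) {
    idx <- ((g - 1L) * Cg + 1L):(g * Cg)
    m <- x[idx, , , drop = FALSE]
    dim(m) <- c(Cg * Tt, B)
    mu <- colMeans(m)
    va <- colMeans(m * m) - mu^2
    iv <- 1 / sqrt(va + eps)
    xh <- (m - rep(mu, each = Cg * Tt)) * rep(iv, each = Cg * Tt)
    inv[g, ] <- iv
    dim(xh) <- c(Cg, Tt, B)
    xhat[idx, , ] <- xh
  }
  y <- xhat * p$gamma + p$beta  # gamma/beta recycle along channel dim
  list(y = y, cache = list(xhat = xhat, inv = inv, dims = d))
}

groupnorm_bwd <- function(p, cache, gy) {
  d <- cache$dims
  C <- d[1]; Tt <- d[2]; B <- d[3]
  G <- p$groups
  Cg <- C %/% G
  xhat <- cache$xhat
  gx <- array(0, d)
  gym <- gy
  dim(gym) <- c(C, Tt * B)
  xhm <- xhat
  dim(xhm) <- c(C, Tt * B)
  ggamma <- rowSums(gym * xhm)
  gbeta <- rowSums(gym)
  for (g in seq_len(G)) {
    idx <- ((g - 1L) * Cg + 1L):(g * Cg)
    gxh <- gy[idx, , , drop = FALSE] * p$gamma[idx]
    dim(gxh) <- c(Cg * Tt, B)
    xh <- xhat[idx, , , drop = FALSE]
    dim(xh) <- c(Cg * Tt, B)
    N <- Cg * Tt
    m1 <- colMeans(gxh)
    m2 <- colMeans(gxh * xh)
    gm <- (gxh - rep(m1, each = N) - xh * rep(m2, each = N)) *
      rep(cache$inv[g, ], each = N)
    dim(gm) <- c(Cg, Tt, B)
    gx[idx, , ] <- gm
  }
  list(gx = gx, g = list(gamma = ggamma, beta = gbeta, groups = 0))
}

# ---- ReLU ------------------------------------------------------------------

relu_fwd <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bwd <- function(cache, gy) gy * cache

# ---- squeeze-and-excitation ------------------------------------------------

se_init <- function(C) {
  if (C < 2L) stop("SE block requires at least 2 channels", call. = FALSE)
  Ch <- C %/% 2L
  # small positive hidden bias: keeps the ReLU bottleneck from starting dead
  list(W1 = matrix(stats::rnorm(Ch * C, 0, sqrt(2 / C)), Ch, C),
       b1 = rep(0.1, Ch),
       W2 = matrix(stats::rnorm(C * Ch, 0, sqrt(2 / Ch)), C, Ch),
       b2 = numeric(C))
}

#' Squeeze-and-excitation channel reweighting
#'
#' Global average pooling over time gives one context value per channel; two
#' dense stages (channel reduction by half, ReLU, restoration, sigmoid) yield
#' per-channel weights in (0, 1) that rescale the input — a channel-attention
#' mechanism with the weight constant over time.
#'
#' @param p Parameters from the internal initializer (`W1`, `b1`, `W2`, `b2`).
#' @param x Input array of dim `c(channels, time, batch)`.
#' @return A list with the output array `y`, the channel weights `w`
#'   (channels x batch), and a `cache`.
#' @keywords internal
#' @export
se_fwd <- function(p, x) {
  d <- dim(x)
  C <- d[1]; Tt <- d[2]; B <- d[3]
  s <- colSums(aperm(x, c(2, 1, 3)), dims = 1) / Tt
  dim(s) <- c(C, B)
  z1 <- p$W1 %*% s + p$b1
  h <- pmax(z1, 0)
  z2 <- p$W2 %*% h + p$b2
  w <- nn_sigmoid(z2)
  warr <- aperm(array(w, c(C, B, Tt)), c(1, 3, 2))
  list(y = x * warr, w = w,
       cache = list(x = x, s = s, z1 = z1, h = h, w = w, warr = warr,
                    dims = d))
}

se_bwd <- function(p, cache, gy) {
  d <- cache$dims
  C <- d[1]; Tt <- d[2]; B <- d[3]
  gx <- gy * cache$warr
  gw <- colSums(aperm(gy * cache$x, c(2, 1, 3)), dims = 1)
  dim(gw) <- c(C, B)
  gz2 <- gw * cache$w * (1 - cache$w)
  gW2 <- tcrossprod(gz2, cache$h)
  gb2 <- rowSums(gz2)
  gh <- crossprod(p$W2, gz2)
  gz1 <- gh * (cache$z1 > 0)
  gW1 <- tcrossprod(gz1, cache$s)
  gb1 <- rowSums(gz1)
  gs <- crossprod(p$W1, gz1)
  gx <- gx + aperm(array(gs / Tt, c(C, B, Tt)), c(1, 3, 2))
  list(gx = gx, g = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

# ---- PPG block: [GatedConv -> GroupNorm -> ReLU] x2 -> SE ------------------

ppg_block_init <- function(cin, cout, groups = 8L, k = 3L) {
  list(gc1 = gated_conv_init(cin, cout, k),
       gn1 = groupnorm_init(cout, groups),
       gc2 = gated_conv_init(cout, cout, k),
       gn2 = groupnorm_init(cout, groups),
       se = se_init(cout))
}

#' Forward pass of one PPG block
#'
#' Two gated-convolution + GroupNorm + ReLU stages followed by a
#' squeeze-and-excitation block; the time length is preserved (kernel 3,
#' stride 1, padding 1).
#'
#' @param p Block parameters from the internal initializer.
#' @param x Input array of dim `c(channels_in, time, batch)`.
#' @return A list with output `y` of dim `c(channels_out, time, batch)` and a
#'   `cache`.
#' @keywords internal
#' @export
ppg_block_fwd <- function(p, x) {
  f1 <- gated_conv_fwd(p$gc1, x)
  n1 <- groupnorm_fwd(p$gn1, f1$y)
  r1 <- relu_fwd(n1$y)
  f2 <- gated_conv_fwd(p$gc2, r1$y)
  n2 <- groupnorm_fwd(p$gn2, f2$y)
  r2 <- relu_fwd(n2$y)
  se <- se_fwd(p$se, r2$y)
  list(y = se$y, cache = list(f1 = f1$cache, n1 = n1$cache, r1 = r1$cache,
                              f2 = f2$cache, n2 = n2$cache, r2 = r2$cache,
                              se = se$cache))
}

ppg_block_bwd <- function(p, cache, gy) {
  bse <- se_bwd(p$se, cache$se, gy)
  g <- relu_bwd(cache$r2, bse$gx)
  bn2 <- groupnorm_bwd(p$gn2, cache$n2, g)
  bf2 <- gated_conv_bwd(p$gc2, cache$f2, bn2$gx)
  g <- relu_bwd(cache$r1, bf2$gx)
  bn1 <- groupnorm_bwd(p$gn1, cache$n1, g)
  bf1 <- gated_conv_bwd(p$gc1, cache$f1, bn1$gx)
  list(gx = bf1$gx,
       g = list(gc1 = bf1$g, gn1 = bn1$g, gc2 = bf2$g, gn2 = bn2$g,
                se = bse$g))
}

# ---- max pooling x2 / linear upsampling x2 ---------------------------------

maxpool2_fwd <- function(x) {
  d <- dim(x)
  stopifnot(d[2] %% 2L == 0L)
  odd <- seq(1L, d[2], by = 2L)
  x1 <- x[, odd, , drop = FALSE]
  x2 <- x[, odd + 1L, , drop = FALSE]
  mask <- x1 >= x2
  list(y = pmax(x1, x2), cache = list(mask = mask, dims = d))
}

maxpool2_bwd <- function(cache, gy) {
  d <- cache$dims
  gx <- array(0, d)
  odd <- seq(1L, d[2], by = 2L)
  gx[, odd, ] <- gy * cache$mask
  gx[, odd + 1L, ] <- gy * !cache$mask
  gx
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  C <- d[1]; Tt <- d[2]; B <- d[3]
  y <- array(0, c(C, 2L * Tt, B))
  odd <- seq(1L, 2L * Tt, by = 2L)
  y[, odd, ] <- x
  xn <- x[, c(seq_len(Tt)[-1], Tt), , drop = FALSE]  # shifted, edge clamped
  y[, odd + 1L, ] <- (x + xn) / 2
  list(y = y, cache = d)
}

upsample2_bwd <- function(cache, gy) {
  d <- cache
  Tt <- d[2]
  odd <- seq(1L, 2L * Tt, by = 2L)
  go <- gy[, odd, , drop = FALSE]
  ge <- gy[, odd + 1L, , drop = FALSE]
  gx <- go
  if (Tt > 1L) {
    gx[, seq_len(Tt - 1L), ] <- gx[, seq_len(Tt - 1L), , drop = FALSE] +
      0.5 * ge[, seq_len(Tt - 1L), , drop = FALSE]
    gx[, 2:Tt, ] <- gx[, 2:Tt, , drop = FALSE] +
      0.5 * ge[, seq_len(Tt - 1L), , drop = FALSE]
    gx[, Tt, ] <- gx[, Tt, , drop = FALSE] + ge[, Tt, , drop = FALSE]
  } else {
    gx[, 1L, ] <- gx[, 1L, , drop = FALSE] + ge[, 1L, , drop = FALSE]
  }
  gx
}

# ---- dense (used per-timestep as a 1x1 projection, or on vectors) ----------

dense_init <- function(cin, cout) {
  sd <- sqrt(2 / (cin + cout))
  list(W = matrix(stats::rnorm(cout * cin, 0, sd), cout, cin),
       b = numeric(cout))
}

dense_ts_fwd <- function(p, x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1], d[2] * d[3])
  y <- p$W %*% xm + p$b
  dim(y) <- c(nrow(p$W), d[2], d[3])
  list(y = y, cache = list(x = x))
}

dense_ts_bwd <- function(p, cache, gy) {
  d <- dim(cache$x)
  xm <- cache$x
  dim(xm) <- c(d[1], d[2] * d[3])
  gym <- gy
  dim(gym) <- c(nrow(p$W), d[2] * d[3])
  gx <- crossprod(p$W, gym)
  dim(gx) <- d
  list(gx = gx, g = list(W = tcrossprod(gym, xm), b = rowSums(gym)))
}

dense_fwd <- function(p, x) list(y = p$W %*% x + p$b, cache = list(x = x))

dense_bwd <- function(p, cache, gy) {
  list(gx = crossprod(p$W, gy),
       g = list(W = tcrossprod(gy, cache$x), b = rowSums(gy)))
}

# ---- bidirectional LSTM over the time axis ---------------------------------

lstm_dir_init <- function(C, H) {
  s <- 1 / sqrt(H)
  b <- numeric(4L * H)
  b[(H + 1L):(2L * H)] <- 1  # forget-gate bias
  list(Wx = matrix(stats::runif(4L * H * C, -s, s), 4L * H, C),
       Wh = matrix(stats::runif(4L * H * H, -s, s), 4L * H, H),
       b = b)
}

lstm_dir_fwd <- function(p, x, reverse = FALSE) {
  d <- dim(x)
  C <- d[1]; Tt <- d[2]; B <- d[3]
  H <- length(p$b) %/% 4L
  ts <- if (reverse) rev(seq_len(Tt)) else seq_len(Tt)
  Hs <- array(0, c(H, Tt, B))
  I <- array(0, c(H, Tt, B)); Fg <- I; G <- I; O <- I; Cc <- I; Tc <- I
  h <- matrix(0, H, B)
  cc <- matrix(0, H, B)
  i1 <- 1:H; i2 <- (H + 1L):(2L * H); i3 <- (2L * H + 1L):(3L * H)
  i4 <- (3L * H + 1L):(4L * H)
  for (t in ts) {
    xt <- matrix(x[, t, ], nrow = C)
    a <- p$Wx %*% xt + p$Wh %*% h + p$b
    ig <- nn_sigmoid(a[i1, , drop = FALSE])
    fg <- nn_sigmoid(a[i2, , drop = FALSE])
    gg <- tanh(a[i3, , drop = FALSE])
    og <- nn_sigmoid(a[i4, , drop = FALSE])
    cc <- fg * cc + ig * gg
    tc <- tanh(cc)
    h <- og * tc
    I[, t, ] <- ig; Fg[, t, ] <- fg; G[, t, ] <- gg; O[, t, ] <- og
    Cc[, t, ] <- cc; Tc[, t, ] <- tc; Hs[, t, ] <- h
  }
  list(y = Hs, cache = list(x = x, I = I, Fg = Fg, G = G, O = O, Cc = Cc,
                            Tc = Tc, Hs = Hs, ts = ts, H = H))
}

lstm_dir_bwd <- function(p, cache, gH) {
  x <- cache$x
  d <- dim(x)
  C <- d[1]; Tt <- d[2]; B <- d[3]
  H <- cache$H
  ts <- cache$ts
  gWx <- p$Wx * 0; gWh <- p$Wh * 0; gb <- p$b * 0
  gx <- array(0, d)
  gh_next <- matrix(0, H, B)
  gc_next <- matrix(0, H, B)
  mat <- function(a, t) matrix(a[, t, ], nrow = dim(a)[1])
  for (s in rev(seq_along(ts))) {
    t <- ts[s]
    tprev <- if (s > 1L) ts[s - 1L] else NA_integer_
    h_prev <- if (is.na(tprev)) matrix(0, H, B) else mat(cache$Hs, tprev)
    c_prev <- if (is.na(tprev)) matrix(0, H, B) else mat(cache$Cc, tprev)
    ig <- mat(cache$I, t); fg <- mat(cache$Fg, t); gg <- mat(cache$G, t)
    og <- mat(cache$O, t); tc <- mat(cache$Tc, t)
    gh <- matrix(gH[, t, ], nrow = H) + gh_next
    go <- gh * tc
    gc <- gh * og * (1 - tc^2) + gc_next
    gi <- gc * gg
    gg2 <- gc * ig
    gf <- gc * c_prev
    gc_next <- gc * fg
    ga <- rbind(gi * ig * (1 - ig),
                gf * fg * (1 - fg),
                gg2 * (1 - gg^2),
                go * og * (1 - og))
    xt <- matrix(x[, t, ], nrow = C)
    gWx <- gWx + tcrossprod(ga, xt)
    gWh <- gWh + tcrossprod(ga, h_prev)
    gb <- gb + rowSums(ga)
    gx[, t, ] <- gx[, t, , drop = FALSE] +
      array(crossprod(p$Wx, ga), c(C, 1L, B))
    gh_next <- crossprod(p$Wh, ga)
  }
  list(gx = gx, g = list(Wx = gWx, Wh = gWh, b = gb))
}

bilstm_init <- function(C, H) {
  list(fwd = lstm_dir_init(C, H), bwd = lstm_dir_init(C, H))
}

bilstm_fwd <- function(p, x) {
  ff <- lstm_dir_fwd(p$fwd, x, reverse = FALSE)
  fb <- lstm_dir_fwd(p$bwd, x, reverse = TRUE)
  d <- dim(ff$y)
  H <- d[1]
  y <- array(0, c(2L * H, d[2], d[3]))
  y[1:H, , ] <- ff$y
  y[(H + 1L):(2L * H), , ] <- fb$y
  list(y = y, cache = list(cf = ff$cache, cb = fb$cache, H = H))
}

bilstm_bwd <- function(p, cache, gy) {
  H <- cache$H
  bf <- lstm_dir_bwd(p$fwd, cache$cf, gy[1:H, , , drop = FALSE])
  bb <- lstm_dir_bwd(p$bwd, cache$cb,
                     gy[(H + 1L):(2L * H), , , drop = FALSE])
  list(gx = bf$gx + bb$gx, g = list(fwd = bf$g, bwd = bb$g))
}

# ---- nested-list parameter utilities ---------------------------------------
# Parameter trees are nested named lists of numeric leaves. The names below
# are structural constants (kernel size, group count), not trainable
# parameters; every tree walker skips them.

.nn_structural <- c("k", "groups")

nl_walk <- function(p, f, path_name = "") {
  if (is.list(p)) {
    out <- p
    nms <- names(p)
    for (i in seq_along(p)) out[[i]] <- nl_walk(p[[i]], f, nms[i])
    out
  } else if (is.numeric(p) && !(path_name %in% .nn_structural)) {
    f(p)
  } else {
    p
  }
}

nl_count <- function(p, path_name = "") {
  if (is.list(p)) {
    nms <- names(p)
    sum(vapply(seq_along(p),
               function(i) nl_count(p[[i]], nms[i]), numeric(1)))
  } else if (is.numeric(p) && !(path_name %in% .nn_structural)) {
    length(p)
  } else 0
}

nl_zero <- function(p) nl_walk(p, function(x) x * 0)

nl_add <- function(a, b, path_name = "") {
  if (is.list(a)) {
    out <- a
    nms <- names(a)
    for (i in seq_along(a)) out[[i]] <- nl_add(a[[i]], b[[i]], nms[i])
    out
  } else if (is.numeric(a) && !(path_name %in% .nn_structural)) {
    a + b
  } else a
}

nl_any_bad <- function(p, path_name = "") {
  if (is.list(p)) {
    nms <- names(p)
    any(vapply(seq_along(p),
               function(i) nl_any_bad(p[[i]], nms[i]), logical(1)))
  } else if (is.numeric(p) && !(path_name %in% .nn_structural)) {
    anyNA(p) || any(!is.finite(p))
  } else FALSE
}
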