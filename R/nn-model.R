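# The restoration generator is a U-shaped gated-convolutional
# encoder-decoder: `depth` PPG blocks with x2 max-pooling on the way down, a
# bidirectional LSTM + dense projection in the latent space, and a mirrored
# decoder with x2 linear-interpolation upsampling and concatenation skip
# connections; a final 3-tap convolution and sigmoid bound the output to
# [0, 1]. The discriminator reuses the encoder stack, global-average-pools
# over time and projects to a single raw score (hinge loss works on raw
# scores, so there is no output nonlinearity).

#' Generator / discriminator architecture configuration
#'
#' @param depth Number of PPG blocks per side.
#' @param channels Channel progression, one entry per block
#'   (`length(channels) == depth`).
#' @param kernel Convolution kernel size (stride 1, padding
#'   `(kernel - 1) / 2`).
#' @param lstm_hidden Hidden size per LSTM direction in the latent stage.
#' @param gn_groups GroupNorm group count (capped at the channel count).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(depth = 3L, channels = c(32L, 64L, 128L),
                             kernel = 3L, lstm_hidden = 128L,
                             gn_groups = 8L) {
  if (length(channels) != depth)
    stop("`depth` must equal `length(channels)`", call. = FALSE)
  if (kernel %% 2L != 1L) stop("`kernel` must be odd", call. = FALSE)
  structure(list(depth = as.integer(depth), channels = as.integer(channels),
                 kernel = as.integer(kernel),
                 lstm_hidden = as.integer(lstm_hidden),
                 gn_groups = as.integer(gn_groups)),
            class = "generator_config")
}

#' Build the restoration generator
#'
#' Initializes all parameters from `seed` (identical seeds give identical
#' initial parameters). The generator maps a window of length T to an output
#' of the same length with values in (0, 1); inputs whose length is not
#' divisible by `2^depth` are reflect-padded internally and cropped back.
#'
#' @param cfg A [generator_config()].
#' @param seed Integer RNG seed for initialization.
#' @return An object of class `ppg_generator` with fields `config`, `params`.
#' @export
build_generator <- function(cfg = generator_config(), seed = 1L) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(seed, {
    ch <- cfg$channels
    d <- cfg$depth
    enc <- vector("list", d)
    for (i in seq_len(d)) {
      cin <- if (i == 1L) 1L else ch[i - 1L]
      enc[[i]] <- ppg_block_init(cin, ch[i], cfg$gn_groups, cfg$kernel)
    }
    dec <- vector("list", d)
    for (j in seq_len(d)) {
      cs <- ch[d - j + 1L]
      cin_up <- if (j == 1L) ch[d] else ch[d - j + 2L]
      dec[[j]] <- list(up = conv_init(cin_up, cs, cfg$kernel),
                       block = ppg_block_init(2L * cs, cs, cfg$gn_groups,
                                              cfg$kernel))
    }
    params <- list(
      enc = enc,
      lstm = bilstm_init(ch[d], cfg$lstm_hidden),
      proj = dense_init(2L * cfg$lstm_hidden, ch[d]),
      dec = dec,
      head = conv_init(ch[1L], 1L, cfg$kernel))
    structure(list(config = cfg, params = params), class = "ppg_generator")
  })
}

#' @export
print.ppg_generator <- function(x, ...) {
  cat(sprintf("<ppg_generator> depth %d, channels %s, %s parameters\n",
              x$config$depth, paste(x$config$channels, collapse = "/"),
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model A `ppg_generator` or `ppg_discriminator`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  stopifnot(is.list(model), !is.null(model$params))
  as.integer(nl_count(model$params))
}

# reflect-pad the time axis of (C,T,B) to length Tpad
pad_reflect <- function(x, Tpad) {
  d <- dim(x)
  Tt <- d[2]
  if (Tpad == Tt) return(x)
  np <- Tpad - Tt
  idx <- Tt - seq_len(np)           # reflect about the last sample
  idx[idx < 1L] <- 1L
  y <- array(0, c(d[1], Tpad, d[3]))
  y[, seq_len(Tt), ] <- x
  y[, (Tt + 1L):Tpad, ] <- x[, idx, , drop = FALSE]
  y
}

# fold gradients of reflected samples back onto their sources
pad_reflect_bwd <- function(gxp, Tt) {
  d <- dim(gxp)
  Tpad <- d[2]
  gx <- gxp[, seq_len(Tt), , drop = FALSE]
  if (Tpad > Tt) {
    np <- Tpad - Tt
    idx <- Tt - seq_len(np)
    idx[idx < 1L] <- 1L
    for (j in seq_len(np))
      gx[, idx[j], ] <- gx[, idx[j], , drop = FALSE] +
        gxp[, Tt + j, , drop = FALSE]
  }
  gx
}

#' Run the generator on a batch of windows
#'
#' @param model A `ppg_generator`.
#' @param x Input windows: a numeric vector (one window), a `T x B` matrix,
#'   or a `c(1, T, B)` array.
#' @param cache Keep intermediate activations for [generator_backward()]?
#' @return If `cache = FALSE`, a `T x B` matrix of outputs in (0, 1);
#'   otherwise a list `(y, cache)`.
#' @export
generator_forward <- function(model, x, cache = FALSE) {
  stopifnot(inherits(model, "ppg_generator"))
  x <- as_ctb(x)
  d0 <- dim(x)
  Tt <- d0[2]
  dpt <- model$config$depth
  div <- 2L^dpt
  Tpad <- as.integer(ceiling(Tt / div) * div)
  xp <- pad_reflect(x, Tpad)
  p <- model$params

  skips <- vector("list", dpt)
  caches <- list(enc = vector("list", dpt), pool = vector("list", dpt),
                 dec = vector("list", dpt), up = vector("list", dpt),
                 cat_split = integer(dpt))
  h <- xp
  for (i in seq_len(dpt)) {
    bf <- ppg_block_fwd(p$enc[[i]], h)
    skips[[i]] <- bf$y
    pf <- maxpool2_fwd(bf$y)
    caches$enc[[i]] <- bf$cache
    caches$pool[[i]] <- pf$cache
    h <- pf$y
  }
  lf <- bilstm_fwd(p$lstm, h)
  pj <- dense_ts_fwd(p$proj, lf$y)
  caches$lstm <- lf$cache
  caches$proj <- pj$cache
  h <- pj$y
  for (j in seq_len(dpt)) {
    uf <- upsample2_fwd(h)
    cf <- conv_fwd(p$dec[[j]]$up, uf$y)
    skip <- skips[[dpt - j + 1L]]
    cs <- dim(cf$y)[1]
    hcat <- array(0, c(cs + dim(skip)[1], dim(cf$y)[2], dim(cf$y)[3]))
    hcat[seq_len(cs), , ] <- cf$y
    hcat[(cs + 1L):dim(hcat)[1], , ] <- skip
    bf <- ppg_block_fwd(p$dec[[j]]$block, hcat)
    caches$up[[j]] <- list(u = uf$cache, c = cf$cache)
    caches$dec[[j]] <- bf$cache
    caches$cat_split[j] <- cs
    h <- bf$y
  }
  hf <- conv_fwd(p$head, h)
  y <- nn_sigmoid(hf$y)
  caches$head <- hf$cache
  caches$sig <- y
  caches$Tt <- Tt
  caches$Tpad <- Tpad
  out <- y[1, seq_len(Tt), , drop = TRUE]
  out <- matrix(out, nrow = Tt)
  if (!cache) return(out)
  list(y = out, cache = caches)
}

#' Backward pass of the generator
#'
#' Given the gradient of a scalar loss with respect to the generator output,
#' accumulates gradients for every parameter.
#'
#' @param model A `ppg_generator`.
#' @param cache The cache from `generator_forward(..., cache = TRUE)`.
#' @param gy Gradient at the output, `T x B`.
#' @return A nested list of gradients shaped like `model$params`.
#' @export
generator_backward <- function(model, cache, gy) {
  p <- model$params
  dpt <- model$config$depth
  Tt <- cache$Tt
  Tpad <- cache$Tpad
  B <- ncol(gy)
  sig <- cache$sig
  gyp <- array(0, c(1L, Tpad, B))
  gyp[1, seq_len(Tt), ] <- gy
  gz <- gyp * sig * (1 - sig)
  bh <- conv_bwd(p$head, cache$head, gz)
  g <- list(enc = vector("list", dpt), lstm = NULL, proj = NULL,
            dec = vector("list", dpt), head = bh$g)
  gh <- bh$gx
  for (j in rev(seq_len(dpt))) {
    bb <- ppg_block_bwd(p$dec[[j]]$block, cache$dec[[j]], gh)
    cs <- cache$cat_split[j]
    gcat <- bb$gx
    gconv <- gcat[seq_len(cs), , , drop = FALSE]
    gskip <- gcat[(cs + 1L):dim(gcat)[1], , , drop = FALSE]
    bc <- conv_bwd(p$dec[[j]]$up, cache$up[[j]]$c, gconv)
    gu <- upsample2_bwd(cache$up[[j]]$u, bc$gx)
    g$dec[[j]] <- list(up = bc$g, block = bb$g)
    # stash skip gradient for the encoder pass
    cache$gskip[[dpt - j + 1L]] <- gskip
    gh <- gu
  }
  bp <- dense_ts_bwd(p$proj, cache$proj, gh)
  bl <- bilstm_bwd(p$lstm, cache$lstm, bp$gx)
  g$proj <- bp$g
  g$lstm <- bl$g
  gh <- bl$gx
  for (i in rev(seq_len(dpt))) {
    gpool <- maxpool2_bwd(cache$pool[[i]], gh)
    gtot <- gpool + cache$gskip[[i]]
    be <- ppg_block_bwd(p$enc[[i]], cache$enc[[i]], gtot)
    g$enc[[i]] <- be$g
    gh <- be$gx
  }
  g
}

#' Build the discriminator
#'
#' Same encoder stack as the generator, followed by global average pooling
#' over time and a dense layer producing one raw score per window.
#'
#' @inheritParams build_generator
#' @return An object of class `ppg_discriminator`.
#' @export
build_discriminator <- function(cfg = generator_config(), seed = 2L) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(seed, {
    ch <- cfg$channels
    d <- cfg$depth
    enc <- vector("list", d)
    for (i in seq_len(d)) {
      cin <- if (i == 1L) 1L else ch[i - 1L]
      enc[[i]] <- ppg_block_init(cin, ch[i], cfg$gn_groups, cfg$kernel)
    }
    params <- list(enc = enc, out = dense_init(ch[d], 1L))
    structure(list(config = cfg, params = params),
              class = "ppg_discriminator")
  })
}

#' @export
print.ppg_discriminator <- function(x, ...) {
  cat(sprintf("<ppg_discriminator> depth %d, channels %s, %s parameters\n",
              x$config$depth, paste(x$config$channels, collapse = "/"),
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Score windows with the discriminator
#'
#' @param model A `ppg_discriminator`.
#' @param x Windows as for [generator_forward()].
#' @param cache Keep activations for [discriminator_backward()]?
#' @return If `cache = FALSE`, a numeric vector of raw scores (one per
#'   window); otherwise a list `(scores, cache)`.
#' @export
discriminator_forward <- function(model, x, cache = FALSE) {
  stopifnot(inherits(model, "ppg_discriminator"))
  x <- as_ctb(x)
  Tt <- dim(x)[2]
  dpt <- model$config$depth
  div <- 2L^dpt
  Tpad <- as.integer(ceiling(Tt / div) * div)
  xp <- pad_reflect(x, Tpad)
  p <- model$params
  caches <- list(enc = vector("list", dpt), pool = vector("list", dpt))
  h <- xp
  for (i in seq_len(dpt)) {
    bf <- ppg_block_fwd(p$enc[[i]], h)
    pf <- maxpool2_fwd(bf$y)
    caches$enc[[i]] <- bf$cache
    caches$pool[[i]] <- pf$cache
    h <- pf$y
  }
  dh <- dim(h)
  s <- colSums(aperm(h, c(2, 1, 3)), dims = 1) / dh[2]
  dim(s) <- c(dh[1], dh[3])
  of <- dense_fwd(p$out, s)
  caches$gap_dims <- dh
  caches$out <- of$cache
  caches$Tt <- Tt
  scores <- as.numeric(of$y)
  if (!cache) return(scores)
  list(scores = scores, cache = caches)
}

#' Backward pass of the discriminator
#'
#' @param model A `ppg_discriminator`.
#' @param cache Cache from `discriminator_forward(..., cache = TRUE)`.
#' @param gscores Gradient of the loss with respect to each score.
#' @return A list `(g, gx)`: parameter gradients and the gradient with
#'   respect to the input windows (`T x B`), used for the adversarial term of
#'   the generator update.
#' @export
discriminator_backward <- function(model, cache, gscores) {
  p <- model$params
  dpt <- model$config$depth
  dh <- cache$gap_dims
  bo <- dense_bwd(p$out, cache$out, matrix(gscores, nrow = 1L))
  gs <- bo$gx  # (C, B)
  gh <- aperm(array(gs / dh[2], c(dh[1], dh[3], dh[2])), c(1, 3, 2))
  g <- list(enc = vector("list", dpt), out = bo$g)
  for (i in rev(seq_len(dpt))) {
    gpool <- maxpool2_bwd(cache$pool[[i]], gh)
    be <- ppg_block_bwd(p$enc[[i]], cache$enc[[i]], gpool)
    g$enc[[i]] <- be$g
    gh <- be$gx
  }
  gx <- pad_reflect_bwd(gh, cache$Tt)
  gx <- matrix(gx[1, , ], nrow = cache$Tt)
  list(g = g, gx = gx)
}

# ---- AdamW -----------------------------------------------------------------

adamw_init <- function(params) {
  list(m = nl_zero(params), v = nl_zero(params), t = 0L)
}

adamw_update <- function(params, grads, state, lr,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         weight_decay = 0.005) {
  state$t <- state$t + 1L
  t <- state$t
  rec <- function(p, g, m, v, nm = "") {
    if (is.list(p)) {
      nms <- names(p)
      for (i in seq_along(p)) {
        r <- rec(p[[i]], g[[i]], m[[i]], v[[i]], nms[i])
        p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    if (!is.numeric(p) || nm %in% .nn_structural)
      return(list(p = p, m = m, v = v))
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    p <- p - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * p)
    list(p = p, m = m, v = v)
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# ---- checkpointing ----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file with a versioned header carrying the
#' architecture configuration and the parameter state.
#'
#' @param model A `ppg_generator` or `ppg_discriminator`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("ppg_generator", "ppg_discriminator")))
  saveRDS(list(format = "ppgrestore-checkpoint", version = 1L,
               class = class(model)[1], config = model$config,
               params = model$params), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "ppgrestore-checkpoint"))
    stop("not a ppgrestore checkpoint: ", path, call. = FALSE)
  structure(list(config = x$config, params = x$params), class = x$class)
}
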