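# Adversarial training: per batch, one discriminator step (minimize the
# hinge loss on real vs generated windows) and one generator step (minimize
# mean custom loss minus theta * mean discriminator score). AdamW with
# decoupled weight decay; reduce-on-plateau learning-rate schedule and early
# stopping on the validation custom loss; the best-on-validation parameters
# are returned. Everything is driven by a single seed.

#' Training configuration
#'
#' @param lr Initial learning rate.
#' @param beta1,beta2 AdamW moment coefficients.
#' @param weight_decay Decoupled L2 scale.
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience (consecutive epochs without
#'   validation improvement tolerated; `0` stops at the first non-improving
#'   epoch, `Inf` disables early stopping).
#' @param batch_size Windows per batch.
#' @param lr_factor,lr_patience,lr_min Reduce-on-plateau schedule: multiply
#'   the learning rate by `lr_factor` after `lr_patience` epochs without
#'   improvement, never below `lr_min`.
#' @param adversarial Train with the discriminator (set `FALSE` for a
#'   generator-only fit).
#' @param seed Integer RNG seed for shuffling.
#' @param verbose Print one line per epoch.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                         weight_decay = 0.005, max_epochs = 300L,
                         patience = 20, batch_size = 32L,
                         lr_factor = 0.5, lr_patience = 10, lr_min = 1e-5,
                         adversarial = TRUE, seed = 1L, verbose = FALSE) {
  if (lr <= 0) stop("lr must be > 0", call. = FALSE)
  if (max_epochs < 1) stop("max_epochs must be >= 1", call. = FALSE)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs), patience = patience,
                 batch_size = as.integer(batch_size), lr_factor = lr_factor,
                 lr_patience = lr_patience, lr_min = lr_min,
                 adversarial = isTRUE(adversarial), seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

# window pairs -> list(x = reference T x N, y = distorted T x N)
pairs_to_matrices <- function(pairs) {
  if (!length(pairs)) return(list(x = NULL, y = NULL))
  Tt <- length(pairs[[1]]$reference)
  list(x = vapply(pairs, function(w) w$reference, numeric(Tt)),
       y = vapply(pairs, function(w) w$distorted, numeric(Tt)))
}

#' Train the restoration model
#'
#' @param gen A `ppg_generator` from [build_generator()].
#' @param disc A `ppg_discriminator`, or `NULL` for generator-only training
#'   (also controlled by `train_cfg$adversarial`).
#' @param data Either a `ppg_dataset` from [make_dataset()] (its
#'   subject-disjoint train/val splits are used) or a list
#'   `list(train = <pairs>, val = <pairs>)` of [window_pair()] lists
#'   (`val` may be empty; the train loss then drives the schedule).
#' @param fs Sampling rate of the windows; taken from the data if available.
#' @param train_cfg A [train_config()].
#' @param loss_cfg A [loss_config()].
#' @return A list of class `ppg_fit`: `generator` (best-on-validation),
#'   `discriminator`, `history` (one row per epoch: losses, peak-count-regime
#'   fraction, learning rate), `best_epoch`.
#' @export
train_restorer <- function(gen, disc = NULL, data, fs = NULL,
                           train_cfg = train_config(),
                           loss_cfg = loss_config()) {
  stopifnot(inherits(gen, "ppg_generator"))
  if (inherits(data, "ppg_dataset")) {
    tr <- data$pairs[data$split$train]
    va <- data$pairs[data$split$val]
    fs <- data$fs
  } else {
    tr <- data$train
    va <- data$val
    if (is.null(fs)) fs <- tr[[1]]$fs
  }
  if (!length(tr)) stop("no training windows", call. = FALSE)
  adversarial <- train_cfg$adversarial && !is.null(disc)

  trm <- pairs_to_matrices(tr)
  vam <- pairs_to_matrices(va)
  n_tr <- ncol(trm$x)

  g_state <- adamw_init(gen$params)
  d_state <- if (adversarial) adamw_init(disc$params) else NULL
  lr <- train_cfg$lr
  best_val <- Inf
  best_params <- gen$params
  best_epoch <- 0L
  since_improve <- 0L
  since_lr <- 0L
  hist <- list()

  val_loss <- function() {
    src <- if (length(va)) vam else trm
    tot <- 0
    n <- ncol(src$x)
    bs <- max(1L, train_cfg$batch_size)
    for (s in seq(1L, n, by = bs)) {
      idx <- s:min(n, s + bs - 1L)
      z <- generator_forward(gen, src$y[, idx, drop = FALSE])
      for (j in seq_along(idx))
        tot <- tot + custom_loss(z[, j], src$x[, idx[j]], fs, loss_cfg)$value
    }
    tot / n
  }

  with_seed(train_cfg$seed, {
    for (epoch in seq_len(train_cfg$max_epochs)) {
      ord <- sample.int(n_tr)
      ep_lc <- 0
      ep_d <- 0
      ep_alpha <- 0
      n_batches <- 0L
      for (s in seq(1L, n_tr, by = train_cfg$batch_size)) {
        idx <- ord[s:min(n_tr, s + train_cfg$batch_size - 1L)]
        xb <- trm$x[, idx, drop = FALSE]
        yb <- trm$y[, idx, drop = FALSE]
        B <- length(idx)

        gf <- generator_forward(gen, yb, cache = TRUE)
        z <- gf$y

        if (adversarial) {
          # ---- discriminator step
          fr <- discriminator_forward(disc, xb, cache = TRUE)
          ff <- discriminator_forward(disc, z, cache = TRUE)
          d_loss <- hinge_d_loss(fr$scores, ff$scores)
          g_real <- -(fr$scores < 1) / B
          g_fake <- (ff$scores > -1) / B
          br <- discriminator_backward(disc, fr$cache, g_real)
          bf <- discriminator_backward(disc, ff$cache, g_fake)
          d_grads <- nl_add(br$g, bf$g)
          upd <- adamw_update(disc$params, d_grads, d_state, lr,
                              train_cfg$beta1, train_cfg$beta2,
                              weight_decay = train_cfg$weight_decay)
          disc$params <- upd$params
          d_state <- upd$state
          ep_d <- ep_d + d_loss
        }

        # ---- generator step
        gz <- matrix(0, nrow(z), B)
        lc_sum <- 0
        for (j in seq_len(B)) {
          cg <- custom_loss_grad(z[, j], xb[, j], fs, loss_cfg)
          gz[, j] <- cg$grad / B
          lc_sum <- lc_sum + cg$value
          if (cg$regime == "peak_count") ep_alpha <- ep_alpha + 1 / B
        }
        if (adversarial) {
          fa <- discriminator_forward(disc, z, cache = TRUE)
          ba <- discriminator_backward(disc, fa$cache,
                                       rep(-loss_cfg$theta / B, B))
          gz <- gz + ba$gx
        }
        g_grads <- generator_backward(gen, gf$cache, gz)
        if (nl_any_bad(g_grads))
          stop("training diverged (non-finite generator gradient) at epoch ",
               epoch, call. = FALSE)
        upd <- adamw_update(gen$params, g_grads, g_state, lr,
                            train_cfg$beta1, train_cfg$beta2,
                            weight_decay = train_cfg$weight_decay)
        gen$params <- upd$params
        g_state <- upd$state
        ep_lc <- ep_lc + lc_sum / B
        n_batches <- n_batches + 1L
      }
      if (nl_any_bad(gen$params))
        stop("training diverged (non-finite parameters) at epoch ", epoch,
             call. = FALSE)

      vl <- val_loss()
      hist[[epoch]] <- data.frame(
        epoch = epoch, train_lc = ep_lc / n_batches,
        d_loss = if (adversarial) ep_d / n_batches else NA_real_,
        val_lc = vl, regime_frac = ep_alpha / n_batches, lr = lr)
      if (train_cfg$verbose)
        message(sprintf(
          "epoch %3d  train L_C %.5f  val L_C %.5f  D %.4f  alpha!=0 %.2f  lr %.2g",
          epoch, ep_lc / n_batches, vl,
          if (adversarial) ep_d / n_batches else NA, ep_alpha / n_batches,
          lr))

      if (vl < best_val - 1e-12) {
        best_val <- vl
        best_params <- gen$params
        best_epoch <- epoch
        since_improve <- 0L
        since_lr <- 0L
      } else {
        since_improve <- since_improve + 1L
        since_lr <- since_lr + 1L
        if (since_improve > train_cfg$patience) break
        if (since_lr > train_cfg$lr_patience && lr > train_cfg$lr_min) {
          lr <- max(train_cfg$lr_min, lr * train_cfg$lr_factor)
          since_lr <- 0L
        }
      }
    }
  })

  gen$params <- best_params
  structure(list(generator = gen,
                 discriminator = if (adversarial) disc else NULL,
                 history = do.call(rbind, hist), best_epoch = best_epoch),
            class = "ppg_fit")
}

#' @export
print.ppg_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<ppg_fit> %d epoch(s); best epoch %d (val L_C %.5f); final regime_frac %.2f\n",
    nrow(h), x$best_epoch, min(h$val_lc), h$regime_frac[nrow(h)]))
  invisible(x)
}
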