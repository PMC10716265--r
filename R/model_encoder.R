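# DL module A: a 1-D convolutional encoder over one 10-minute window of
# single-lead ECG. Four conv(kernel 7)-ReLU-meanpool(4) blocks, global
# average pooling, then two fully connected layers; the second-last layer
# has width 128 and its activations are the window embedding. The final
# sigmoid unit is trained with recording-level AF labels broadcast to the
# recording's AF-free windows (weak labels); after training the weights
# are frozen and the encoder acts purely as a feature extractor.

#' Configuration of the window encoder (DL module A)
#'
#' @param input_fs sampling rate the encoder consumes, Hz; window signals
#'   at higher rates are mean-bin resampled (default 25).
#' @param widths channel widths of the four conv blocks.
#' @param kernel convolution kernel length (samples).
#' @param pool pooling factor per block (length-4 vector or scalar).
#' @param embed_dim width of the second-last fully connected layer, i.e.
#'   the embedding dimension (128 in the reference design).
#' @param window_sec window length in seconds.
#' @return list of class `af_encoder_config`.
#' @export
encoder_config <- function(input_fs = 25, widths = c(8, 16, 32, 32),
                           kernel = 7, pool = c(8, 4, 4, 4), embed_dim = 128,
                           window_sec = WINDOW_SEC) {
  if (length(pool) == 1) pool <- rep(pool, 4)
  stopifnot(length(widths) == 4, length(pool) == 4, kernel %% 2 == 1, embed_dim >= 1)
  structure(list(
    input_fs = input_fs, widths = widths, kernel = kernel, pool = pool,
    embed_dim = as.integer(embed_dim), window_sec = window_sec,
    input_len = as.integer(window_sec * input_fs)
  ), class = "af_encoder_config")
}

encoder_init <- function(config, seed) {
  k <- config$kernel
  cin <- c(1, config$widths[-4])
  w <- list()
  with_seed(af_subseed(seed, "enc-init"), {
    for (i in 1:4) {
      fan <- cin[i] * k
      w[[paste0("Wc", i)]] <- matrix(
        stats::rnorm(fan * config$widths[i], 0, sqrt(2 / fan)),
        fan, config$widths[i]
      )
      w[[paste0("bc", i)]] <- numeric(config$widths[i])
    }
    c4 <- config$widths[4]
    w$W5 <- matrix(stats::rnorm(c4 * config$embed_dim, 0, sqrt(2 / c4)), c4, config$embed_dim)
    w$b5 <- numeric(config$embed_dim)
    w$W6 <- matrix(stats::rnorm(config$embed_dim, 0, sqrt(1 / config$embed_dim)),
      config$embed_dim, 1)
    w$b6 <- 0
  })
  w
}

# Forward pass for one window (vector of input_len samples, already at
# input_fs). Returns logit, embedding and caches for backprop.
encoder_forward <- function(weights, config, x, want_cache = FALSE) {
  s <- stats::sd(x)
  x <- (x - mean(x)) / if (s > 1e-8) s else 1
  h <- matrix(x, ncol = 1)
  caches <- list()
  for (i in 1:4) {
    cf <- conv1d_forward(h, weights[[paste0("Wc", i)]], weights[[paste0("bc", i)]], config$kernel)
    a <- relu(cf$out)
    pf <- meanpool_forward(a, config$pool[i])
    if (want_cache) caches[[i]] <- list(M = cf$M, pre = cf$out, L_in = pf$L_in, Cin = ncol(h))
    h <- pf$out
  }
  g <- colMeans(h) # global average pool
  e_pre <- drop(g %*% weights$W5) + weights$b5
  e <- relu(e_pre)
  logit <- drop(e %*% weights$W6) + weights$b6
  list(
    logit = logit, embedding = e,
    cache = if (want_cache) list(caches = caches, h4 = h, g = g, e_pre = e_pre, e = e)
  )
}

encoder_backward <- function(weights, config, fw, dlogit) {
  cc <- fw$cache
  g <- list()
  g$W6 <- matrix(cc$e * dlogit, ncol = 1)
  g$b6 <- dlogit
  de <- drop(weights$W6) * dlogit
  de[cc$e_pre <= 0] <- 0
  g$W5 <- outer(cc$g, de)
  g$b5 <- de
  dg <- drop(weights$W5 %*% de)
  L4 <- nrow(cc$h4)
  dh <- matrix(rep(dg / L4, each = L4), L4, length(dg))
  for (i in 4:1) {
    ci <- cc$caches[[i]]
    da <- meanpool_backward(dh, config$pool[i], nrow(ci$pre))
    da[ci$pre <= 0] <- 0
    cb <- conv1d_backward(da, ci$M, weights[[paste0("Wc", i)]], config$kernel, ci$Cin)
    g[[paste0("Wc", i)]] <- cb$dW
    g[[paste0("bc", i)]] <- cb$db
    dh <- cb$dx
  }
  g[names(weights)]
}

#' Train the window encoder (DL module A)
#'
#' Trains the convolutional encoder with binary cross-entropy on weakly
#' labelled windows: each AF-free 10-minute window inherits its
#' recording's AF-positive label. Adam optimizer, early stopping on
#' validation loss; fully deterministic under `seed`.
#'
#' @param windows numeric matrix, one row per window, `input_len` columns
#'   of signal at `config$input_fs`.
#' @param labels 0/1 vector of recording-level AF labels per window.
#' @param config an [encoder_config()].
#' @param seed integer seed.
#' @param epochs maximum epochs (default 8).
#' @param batch minibatch size.
#' @param lr Adam learning rate.
#' @param val_frac fraction of windows held out for early stopping.
#' @param patience epochs without validation improvement before stopping.
#' @param verbose print per-epoch losses.
#' @return object of class `af_encoder`: `weights`, `config`, `history`.
#' @export
train_module_a <- function(windows, labels, config = encoder_config(),
                           seed = 1, epochs = 8, batch = 16, lr = 1e-3,
                           val_frac = 0.15, patience = 2, verbose = FALSE) {
  stopifnot(is.matrix(windows), ncol(windows) == config$input_len)
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2) {
    stop("training labels contain a single class; refusing to train")
  }
  n <- nrow(windows)
  weights <- encoder_init(config, seed)
  state <- adam_init(weights)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0), val_loss = numeric(0))

  with_seed(af_subseed(seed, "enc-train"), {
    val_idx <- sample.int(n, max(2, round(n * val_frac)))
    tr_idx <- setdiff(seq_len(n), val_idx)
    best <- list(loss = Inf, weights = weights, since = 0)
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      tl <- 0
      nb <- 0
      for (bs in split(ord, ceiling(seq_along(ord) / batch))) {
        acc <- NULL
        bl <- 0
        for (i in bs) {
          fw <- encoder_forward(weights, config, windows[i, ], want_cache = TRUE)
          ls <- bce_loss(fw$logit, labels[i])
          bl <- bl + ls$loss
          gr <- encoder_backward(weights, config, fw, ls$dlogit)
          acc <- if (is.null(acc)) gr else Map(`+`, acc, gr)
        }
        acc <- lapply(acc, function(g) g / length(bs))
        upd <- adam_step(weights, acc, state, lr = lr)
        weights <- upd$params
        state <- upd$state
        tl <- tl + bl / length(bs)
        nb <- nb + 1
      }
      vl <- mean(vapply(val_idx, function(i) {
        bce_loss(encoder_forward(weights, config, windows[i, ])$logit, labels[i])$loss
      }, numeric(1)))
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = tl / nb, val_loss = vl
      ))
      if (verbose) message(sprintf("module A epoch %d: train %.4f val %.4f", ep, tl / nb, vl))
      if (vl < best$loss - 1e-5) {
        best <- list(loss = vl, weights = weights, since = 0)
      } else {
        best$since <- best$since + 1
        if (best$since >= patience) break
      }
    }
    weights <- best$weights
  })
  structure(list(weights = weights, config = config, history = history),
    class = "af_encoder")
}

#' Encode a 10-minute window into its 128-dimensional embedding
#'
#' Runs the frozen encoder and returns the activations of the second-last
#' fully connected layer. Signals sampled faster than the encoder's input
#' rate are mean-bin resampled first (the rate ratio must be an integer).
#'
#' @param signal numeric vector of window samples.
#' @param encoder a trained [train_module_a()] object.
#' @param fs sampling rate of `signal`; defaults to the encoder input rate.
#' @return numeric vector of length `config$embed_dim`.
#' @export
encode_window <- function(signal, encoder, fs = encoder$config$input_fs) {
  x <- resample_to(signal, fs, encoder$config$input_fs)
  if (length(x) != encoder$config$input_len) {
    stop(sprintf("window length %d does not match encoder input length %d",
      length(x), encoder$config$input_len))
  }
  encoder_forward(encoder$weights, encoder$config, x)$embedding
}

#' Window-level AF score from the encoder's own sigmoid head
#'
#' Used for training diagnostics (the encoder is a weakly supervised
#' window classifier before it is frozen as a feature extractor).
#'
#' @inheritParams encode_window
#' @return probability in (0, 1).
#' @export
encoder_window_score <- function(signal, encoder, fs = encoder$config$input_fs) {
  x <- resample_to(signal, fs, encoder$config$input_fs)
  sigmoid(encoder_forward(encoder$weights, encoder$config, x)$logit)
}

#' Exact checksum of encoder weights
#'
#' Used to assert the frozen-encoder property: the checksum must be
#' bit-identical before and after any downstream training.
#'
#' @param encoder an `af_encoder` object.
#' @return named numeric vector (`n`, `sum`, `sumsq`) for exact comparison.
#' @export
encoder_checksum <- function(encoder) {
  v <- unlist(encoder$weights, use.names = FALSE)
  c(n = length(v), sum = sum(v), sumsq = sum(v^2))
}
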