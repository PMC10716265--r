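# DL module B: a 2-layer bidirectional LSTM over the sequence of
# normalized per-window feature vectors, followed by 2 fully connected
# layers. The concatenated final states of the second layer's two
# directions are joined with the (transformed) demographic features and
# mapped to a sigmoid risk score for the whole input interval. The
# demographics-only (AG) configuration bypasses the recurrent stage
# entirely, so two subjects with identical demographics receive exactly
# equal scores regardless of their ECG.

HRV_FEATURES <- c(
  "mean_nn", "median_nn", "sdnn", "rmssd", "pnn50", "sdsd", "cv_nn",
  "mean_hr", "min_hr", "max_hr", "tri_index", "lf_power", "hf_power",
  "lf_hf_ratio", "total_power"
)
ECTOPIC_FEATURES <- c("pac_count", "pvc_count", "pac_per_min", "pvc_per_min")
RHYTHM_FEATURES <- c("svt_burden", "avb_burden", "artifact_frac")

# column order of window_features(): 15 HRV metrics then rhythm/ectopic
HANDCRAFTED_FEATURES <- c(
  HRV_FEATURES, "svt_burden", "avb_burden", "artifact_frac",
  "pac_count", "pvc_count", "pac_per_min", "pvc_per_min"
)

FEATURE_SET_NAMES <- c(
  "AG", "AG+HRV", "AG+Ectopic", "AG+HRV+Ectopic+Rhythm",
  "DL Only", "All Features"
)

#' Input configuration of the AF prediction model
#'
#' The six named input configurations: `AG` (age and sex only), `AG+HRV`,
#' `AG+Ectopic`, `AG+HRV+Ectopic+Rhythm`, `DL Only` (the 128 learned
#' window-embedding features only, no demographics), and `All Features`.
#'
#' @param name one of the six configuration names.
#' @return list of class `af_feature_set`: `name`, `groups` (sequence
#'   feature groups among `hrv`, `ectopic`, `rhythm`, `embedding`),
#'   `use_demo` (append demographics at the head).
#' @export
af_feature_set <- function(name) {
  name <- match.arg(name, FEATURE_SET_NAMES)
  cfg <- switch(name,
    "AG" = list(groups = character(0), use_demo = TRUE),
    "AG+HRV" = list(groups = "hrv", use_demo = TRUE),
    "AG+Ectopic" = list(groups = "ectopic", use_demo = TRUE),
    "AG+HRV+Ectopic+Rhythm" = list(groups = c("hrv", "ectopic", "rhythm"), use_demo = TRUE),
    "DL Only" = list(groups = "embedding", use_demo = FALSE),
    "All Features" = list(
      groups = c("hrv", "ectopic", "rhythm", "embedding"), use_demo = TRUE
    )
  )
  structure(c(list(name = name), cfg), class = "af_feature_set")
}

#' Column names of a sequence feature group
#'
#' @param group one of `hrv`, `ectopic`, `rhythm`, `embedding`.
#' @param available all available feature column names (used to resolve
#'   the embedding columns `emb_1..emb_K`).
#' @return character vector of column names.
#' @export
feature_group_columns <- function(group, available) {
  switch(group,
    hrv = HRV_FEATURES,
    ectopic = ECTOPIC_FEATURES,
    rhythm = RHYTHM_FEATURES,
    embedding = grep("^emb_", available, value = TRUE),
    stop(sprintf("unknown feature group '%s'", group))
  )
}

#' Sequence-input column names for a feature-set configuration
#'
#' @param fset an [af_feature_set()].
#' @param available all available feature column names.
#' @return character vector (possibly empty, for the AG configuration).
#' @export
feature_set_columns <- function(fset, available) {
  out <- unlist(lapply(fset$groups, feature_group_columns, available = available),
    use.names = FALSE)
  if (is.null(out)) character(0) else out
}

# ---- LSTM primitives -------------------------------------------------------

lstm_forward <- function(X, W, U, b) {
  T_ <- nrow(X); H <- nrow(U)
  h <- numeric(H); c <- numeric(H)
  Hout <- matrix(0, T_, H)
  cache <- vector("list", T_)
  for (t in seq_len(T_)) {
    z <- drop(X[t, ] %*% W) + drop(h %*% U) + b
    i <- sigmoid(z[1:H])
    f <- sigmoid(z[(H + 1):(2 * H)])
    g <- tanh(z[(2 * H + 1):(3 * H)])
    o <- sigmoid(z[(3 * H + 1):(4 * H)])
    c_new <- f * c + i * g
    hc <- tanh(c_new)
    cache[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = c, hc = hc, h_prev = h)
    c <- c_new
    h <- o * hc
    Hout[t, ] <- h
  }
  list(H = Hout, cache = cache)
}

lstm_backward <- function(X, W, U, fw, dH) {
  T_ <- nrow(X); H <- nrow(U); D <- ncol(X)
  dW <- matrix(0, D, 4 * H); dU <- matrix(0, H, 4 * H); db <- numeric(4 * H)
  dX <- matrix(0, T_, D)
  dh_next <- numeric(H); dc_next <- numeric(H)
  for (t in rev(seq_len(T_))) {
    cc <- fw$cache[[t]]
    dh <- dH[t, ] + dh_next
    do_ <- dh * cc$hc
    dc <- dc_next + dh * cc$o * (1 - cc$hc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc_next <- dc * cc$f
    dz <- c(
      di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
      dg * (1 - cc$g^2), do_ * cc$o * (1 - cc$o)
    )
    dW <- dW + outer(X[t, ], dz)
    dU <- dU + outer(cc$h_prev, dz)
    db <- db + dz
    dX[t, ] <- drop(W %*% dz)
    dh_next <- drop(U %*% dz)
  }
  list(dX = dX, dW = dW, dU = dU, db = db)
}

bilstm_forward <- function(X, wf, wb) {
  T_ <- nrow(X)
  f <- lstm_forward(X, wf$W, wf$U, wf$b)
  Xr <- X[rev(seq_len(T_)), , drop = FALSE]
  b <- lstm_forward(Xr, wb$W, wb$U, wb$b)
  list(
    out = cbind(f$H, b$H[rev(seq_len(T_)), , drop = FALSE]),
    f = f, b = b, X = X, Xr = Xr
  )
}

bilstm_backward <- function(fw, wf, wb, dOut) {
  T_ <- nrow(fw$X); H <- nrow(wf$U)
  gf <- lstm_backward(fw$X, wf$W, wf$U, fw$f, dOut[, 1:H, drop = FALSE])
  dHb_r <- dOut[rev(seq_len(T_)), (H + 1):(2 * H), drop = FALSE]
  gb <- lstm_backward(fw$Xr, wb$W, wb$U, fw$b, dHb_r)
  list(
    dX = gf$dX + gb$dX[rev(seq_len(T_)), , drop = FALSE],
    f = gf, b = gb
  )
}

# ---- module B model --------------------------------------------------------

init_module_b <- function(feature_names, demo_dim, H, head_dim, seed) {
  D <- length(feature_names)
  w <- list()
  mk_dir <- function(dir, layer, names_in, D_in) {
    W <- matrix(0, D_in, 4 * H)
    if (layer == 1) {
      for (fi in seq_len(D_in)) {
        for (j in seq_len(4 * H)) {
          W[fi, j] <- keyed_normal(seed, "W1", dir, names_in[fi], j, sd = sqrt(1 / D_in))
        }
      }
    } else {
      W[] <- with_seed(
        af_subseed(seed, "W", layer, dir),
        stats::rnorm(D_in * 4 * H, 0, sqrt(1 / D_in))
      )
    }
    U <- with_seed(
      af_subseed(seed, "U", layer, dir),
      matrix(stats::rnorm(H * 4 * H, 0, sqrt(1 / H)), H, 4 * H)
    )
    b <- numeric(4 * H)
    b[(H + 1):(2 * H)] <- 1 # forget-gate bias
    list(W = W, U = U, b = b)
  }
  if (D > 0) {
    w$l1f <- mk_dir("f", 1, feature_names, D)
    w$l1b <- mk_dir("b", 1, feature_names, D)
    w$l2f <- mk_dir("f", 2, NULL, 2 * H)
    w$l2b <- mk_dir("b", 2, NULL, 2 * H)
  }
  z_dim <- (if (D > 0) 2 * H else 0) + demo_dim
  with_seed(af_subseed(seed, "head"), {
    w$Wh1 <- matrix(stats::rnorm(z_dim * head_dim, 0, sqrt(2 / z_dim)), z_dim, head_dim)
    w$bh1 <- numeric(head_dim)
    w$Wh2 <- matrix(stats::rnorm(head_dim, 0, sqrt(1 / head_dim)), head_dim, 1)
    w$bh2 <- 0
  })
  w
}

# Flatten/unflatten nested weights for the Adam optimizer.
flatten_w <- function(w) {
  out <- list()
  for (nm in names(w)) {
    if (is.list(w[[nm]])) {
      for (p in names(w[[nm]])) out[[paste0(nm, ".", p)]] <- w[[nm]][[p]]
    } else {
      out[[nm]] <- w[[nm]]
    }
  }
  out
}

unflatten_w <- function(flat) {
  w <- list()
  for (nm in names(flat)) {
    if (grepl("\\.", nm)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      if (is.null(w[[parts[1]]])) w[[parts[1]]] <- list()
      w[[parts[1]]][[parts[2]]] <- flat[[nm]]
    } else {
      w[[nm]] <- flat[[nm]]
    }
  }
  w
}

module_b_forward <- function(w, X, demo, H, want_cache = FALSE) {
  uses_seq <- !is.null(X) && nrow(X) > 0 && ncol(X) > 0
  if (uses_seq) {
    l1 <- bilstm_forward(X, w$l1f, w$l1b)
    l2f <- lstm_forward(l1$out, w$l2f$W, w$l2f$U, w$l2f$b)
    L1r <- l1$out[rev(seq_len(nrow(l1$out))), , drop = FALSE]
    l2b <- lstm_forward(L1r, w$l2b$W, w$l2b$U, w$l2b$b)
    rep_ <- c(l2f$H[nrow(X), ], l2b$H[nrow(X), ])
    z <- c(rep_, demo)
  } else {
    z <- demo
  }
  a_pre <- drop(z %*% w$Wh1) + w$bh1
  a <- relu(a_pre)
  logit <- drop(a %*% w$Wh2) + w$bh2
  list(
    logit = logit,
    cache = if (want_cache) {
      list(uses_seq = uses_seq, z = z, a_pre = a_pre, a = a,
        l1 = if (uses_seq) l1, l2f = if (uses_seq) l2f,
        l2b = if (uses_seq) l2b, L1r = if (uses_seq) L1r, X = X)
    }
  )
}

module_b_backward <- function(w, fw, dlogit, H) {
  cc <- fw$cache
  g <- list()
  g$Wh2 <- matrix(cc$a * dlogit, ncol = 1)
  g$bh2 <- dlogit
  da <- drop(w$Wh2) * dlogit
  da[cc$a_pre <= 0] <- 0
  g$Wh1 <- outer(cc$z, da)
  g$bh1 <- da
  dz <- drop(w$Wh1 %*% da)
  if (cc$uses_seq) {
    T_ <- nrow(cc$X)
    drep <- dz[1:(2 * H)]
    dH2f <- matrix(0, T_, H); dH2f[T_, ] <- drep[1:H]
    dH2b <- matrix(0, T_, H); dH2b[T_, ] <- drep[(H + 1):(2 * H)]
    g2f <- lstm_backward(cc$l1$out, w$l2f$W, w$l2f$U, cc$l2f, dH2f)
    g2b <- lstm_backward(cc$L1r, w$l2b$W, w$l2b$U, cc$l2b, dH2b)
    dL1 <- g2f$dX + g2b$dX[rev(seq_len(T_)), , drop = FALSE]
    g1 <- bilstm_backward(cc$l1, w$l1f, w$l1b, dL1)
    g$l2f <- list(W = g2f$dW, U = g2f$dU, b = g2f$db)
    g$l2b <- list(W = g2b$dW, U = g2b$dU, b = g2b$db)
    g$l1f <- list(W = g1$f$dW, U = g1$f$dU, b = g1$f$db)
    g$l1b <- list(W = g1$b$dW, U = g1$b$dU, b = g1$b$db)
  }
  g
}

#' Train the sequence risk model (DL module B)
#'
#' Trains the 2-layer bidirectional LSTM + 2 fully connected layers on
#' sequences of normalized per-window feature vectors with recording-level
#' AF labels and binary cross-entropy. Sequences may have any length from
#' 1 window (10 min) up to 144 (24 h); during training each example is
#' randomly truncated to a prefix so that one model serves all input
#' lengths. The AG configuration (no sequence features) degenerates to a
#' fully connected head on demographics alone.
#'
#' @param sequences list of `T x D` matrices of (already transformed)
#'   window features, columns named; or `NULL` for the AG configuration.
#' @param demo `n x d` matrix of transformed demographic features
#'   (e.g. standardized age and 0/1 sex); may have zero columns for the
#'   DL-Only configuration.
#' @param labels 0/1 AF-positive recording labels.
#' @param hidden LSTM hidden width per direction.
#' @param head_dim width of the first fully connected head layer.
#' @param seed integer seed.
#' @param epochs,batch,lr,val_frac,patience training hyper-parameters
#'   (Adam, early stopping on validation loss).
#' @param len_augment randomly truncate sequences during training.
#' @param verbose print per-epoch losses.
#' @return object of class `af_sequence_model`.
#' @export
train_module_b <- function(sequences, demo, labels, hidden = 16, head_dim = 16,
                           seed = 1, epochs = 30, batch = 16, lr = 1e-3,
                           val_frac = 0.15, patience = 4, len_augment = TRUE,
                           verbose = FALSE) {
  labels <- as.numeric(labels)
  n <- length(labels)
  uses_seq <- !is.null(sequences)
  demo <- as.matrix(demo)
  if (!uses_seq && ncol(demo) == 0) {
    stop("configuration with neither sequence features nor demographics is rejected")
  }
  if (length(unique(labels)) < 2) {
    stop("training labels contain a single class; refusing to train")
  }
  feature_names <- if (uses_seq) colnames(sequences[[1]]) else character(0)
  w <- init_module_b(feature_names, ncol(demo), hidden, head_dim, seed)
  flat <- flatten_w(w)
  state <- adam_init(flat)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0), val_loss = numeric(0))

  ex_loss <- function(w, i, len = NULL) {
    X <- if (uses_seq) {
      Ti <- nrow(sequences[[i]])
      L <- if (is.null(len)) Ti else min(len, Ti)
      sequences[[i]][seq_len(L), , drop = FALSE]
    } else {
      NULL
    }
    fw <- module_b_forward(w, X, demo[i, ], hidden, want_cache = TRUE)
    ls <- bce_loss(fw$logit, labels[i])
    list(fw = fw, ls = ls)
  }

  with_seed(af_subseed(seed, "b-train"), {
    val_idx <- sample.int(n, max(2, round(n * val_frac)))
    tr_idx <- setdiff(seq_len(n), val_idx)
    best <- list(loss = Inf, flat = flat, since = 0)
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      tl <- 0; nb <- 0
      for (bs in split(ord, ceiling(seq_along(ord) / batch))) {
        w <- unflatten_w(flat)
        acc <- NULL
        bl <- 0
        for (i in bs) {
          len <- if (uses_seq && len_augment) sample.int(nrow(sequences[[i]]), 1) else NULL
          r <- ex_loss(w, i, len)
          bl <- bl + r$ls$loss
          gr <- flatten_w(module_b_backward(w, r$fw, r$ls$dlogit, hidden))
          gr <- gr[names(flat)]
          acc <- if (is.null(acc)) gr else Map(`+`, acc, gr)
        }
        acc <- lapply(acc, function(g) g / length(bs))
        upd <- adam_step(flat, acc, state, lr = lr)
        flat <- upd$params
        state <- upd$state
        tl <- tl + bl / length(bs)
        nb <- nb + 1
      }
      w <- unflatten_w(flat)
      vl <- mean(vapply(val_idx, function(i) ex_loss(w, i)$ls$loss, numeric(1)))
      history <- rbind(history, data.frame(epoch = ep, train_loss = tl / nb, val_loss = vl))
      if (verbose) message(sprintf("module B epoch %d: train %.4f val %.4f", ep, tl / nb, vl))
      if (vl < best$loss - 1e-5) {
        best <- list(loss = vl, flat = flat, since = 0)
      } else {
        best$since <- best$since + 1
        if (best$since >= patience) break
      }
    }
    flat <- best$flat
  })
  structure(list(
    weights = unflatten_w(flat), hidden = hidden, head_dim = head_dim,
    feature_names = feature_names, demo_dim = ncol(demo),
    uses_seq = uses_seq, history = history
  ), class = "af_sequence_model")
}

#' Raw AF risk score for one recording's window-feature sequence
#'
#' Deterministic inference: the sigmoid output of module B on the
#' sequence's first `n_windows` windows (all windows by default).
#' Invariant to batch composition (inference is per recording).
#'
#' @param model a trained [train_module_b()] object.
#' @param sequence `T x D` matrix of transformed window features (column
#'   names must match training), or `NULL` for the AG configuration.
#' @param demo transformed demographic vector.
#' @param n_windows optional prefix length (10-min windows) to score.
#' @return risk score strictly inside (0, 1).
#' @export
predict_risk <- function(model, sequence, demo, n_windows = NULL) {
  X <- NULL
  if (model$uses_seq) {
    if (is.null(sequence) || nrow(sequence) == 0) {
      stop("model requires a non-empty window sequence")
    }
    if (!identical(colnames(sequence), model$feature_names)) {
      sequence <- sequence[, model$feature_names, drop = FALSE]
    }
    L <- if (is.null(n_windows)) nrow(sequence) else min(n_windows, nrow(sequence))
    X <- sequence[seq_len(L), , drop = FALSE]
  }
  p <- sigmoid(module_b_forward(model$weights, X, as.numeric(demo), model$hidden)$logit)
  min(max(p, 1e-12), 1 - 1e-12)
}
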