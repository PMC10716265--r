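# Minimal neural-network primitives used by the two deep modules: 1-D
# convolution via im2col + GEMM, mean pooling, dense layers, explicit
# backward passes, and an Adam optimizer. Everything is plain base-R
# matrix algebra (BLAS-backed), fully deterministic given a seed.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# im2col with zero "same" padding: x is L x C, returns L x (C*k), columns
# ordered channel-major then tap.
im2col <- function(x, k) {
  L <- nrow(x); C <- ncol(x)
  p <- (k - 1) %/% 2
  xp <- rbind(
    matrix(0, p, C), x,
    matrix(0, k - 1 - p, C)
  )
  base <- outer(seq_len(L), 0:(k - 1), "+")
  M <- matrix(0, L, C * k)
  for (c in seq_len(C)) {
    col <- xp[, c]
    M[, (c - 1) * k + seq_len(k)] <- col[base]
  }
  M
}

conv1d_forward <- function(x, W, b, k) {
  M <- im2col(x, k)
  out <- M %*% W
  out <- sweep(out, 2, b, "+")
  list(out = out, M = M)
}

conv1d_backward <- function(dout, M, W, k, Cin) {
  L <- nrow(dout)
  p <- (k - 1) %/% 2
  dW <- crossprod(M, dout)
  db <- colSums(dout)
  dM <- dout %*% t(W)
  dxp <- matrix(0, L + k - 1, Cin)
  for (c in seq_len(Cin)) {
    for (j in seq_len(k)) {
      idx <- seq_len(L) + j - 1
      dxp[idx, c] <- dxp[idx, c] + dM[, (c - 1) * k + j]
    }
  }
  dx <- dxp[(p + 1):(p + L), , drop = FALSE]
  list(dW = dW, db = db, dx = dx)
}

meanpool_forward <- function(x, p) {
  L <- nrow(x)
  Lo <- L %/% p
  xt <- x[seq_len(Lo * p), , drop = FALSE]
  out <- rowsum(xt, rep(seq_len(Lo), each = p)) / p
  list(out = out, L_in = L)
}

meanpool_backward <- function(dout, p, L_in) {
  Lo <- nrow(dout)
  dx <- dout[rep(seq_len(Lo), each = p), , drop = FALSE] / p
  if (Lo * p < L_in) dx <- rbind(dx, matrix(0, L_in - Lo * p, ncol(dout)))
  dx
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0
  )
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, clip = 5) {
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(gnorm) && gnorm > clip) {
    grads <- lapply(grads, function(g) g * clip / gnorm)
  }
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    params[[i]] <- params[[i]] -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Binary cross-entropy for a sigmoid output; returns loss and dlogit.
bce_loss <- function(logit, y) {
  p <- sigmoid(logit)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  list(loss = -mean(y * log(p) + (1 - y) * log(1 - p)), dlogit = (p - y))
}

# Mean-bin resampling of a signal from fs_in to fs_out (integer factor).
resample_to <- function(x, fs_in, fs_out) {
  if (fs_in == fs_out) {
    return(x)
  }
  f <- fs_in / fs_out
  if (abs(f - round(f)) > 1e-9 || f < 1) {
    stop(sprintf("sampling rate %g not an integer multiple of encoder rate %g", fs_in, fs_out))
  }
  f <- round(f)
  Lo <- length(x) %/% f
  as.numeric(rowsum(x[seq_len(Lo * f)], rep(seq_len(Lo), each = f)) / f)
}

# Name-keyed Gaussian initial weight: depends on (seed, key path), never on
# column position, so permuting input features permutes rows of the weight
# matrix exactly (representation symmetry).
keyed_normal <- function(seed, ..., sd = 1) {
  u <- hash_unit(seed, ...)
  stats::qnorm(pmin(pmax(u, 1e-7), 1 - 1e-7)) * sd
}
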