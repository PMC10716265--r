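# The two deep modules: gradient correctness, determinism, the frozen
# encoder contract, configuration degeneracies, and representation
# symmetry.

tiny_encoder <- function() {
  encoder_config(
    input_fs = 2, window_sec = 16, widths = c(2, 3, 3, 2),
    kernel = 3, pool = c(2, 2, 2, 2), embed_dim = 5
  )
}

test_that("encoder analytic gradients match finite differences", {
  cfg <- tiny_encoder()
  w <- afhorizon:::encoder_init(cfg, 3)
  set.seed(3)
  x <- rnorm(cfg$input_len)
  y <- 1
  loss_of <- function(w) {
    bce_loss(afhorizon:::encoder_forward(w, cfg, x)$logit, y)$loss
  }
  fw <- afhorizon:::encoder_forward(w, cfg, x, want_cache = TRUE)
  gr <- afhorizon:::encoder_backward(w, cfg, fw, bce_loss(fw$logit, y)$dlogit)
  eps <- 1e-6
  for (nm in c("Wc1", "Wc3", "W5", "W6", "bc2", "b5")) {
    idx <- seq_len(min(6, length(w[[nm]])))
    for (i in idx) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      num <- (loss_of(wp) - loss_of(wm)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("sequence-model analytic gradients match finite differences", {
  set.seed(5)
  fn <- c("f1", "f2", "f3", "f4")
  w <- afhorizon:::init_module_b(fn, demo_dim = 2, H = 3, head_dim = 4, seed = 5)
  X <- matrix(rnorm(12), 3, 4, dimnames = list(NULL, fn))
  demo <- c(0.3, 1)
  y <- 1
  loss_of <- function(w) {
    bce_loss(afhorizon:::module_b_forward(w, X, demo, 3)$logit, y)$loss
  }
  fw <- afhorizon:::module_b_forward(w, X, demo, 3, want_cache = TRUE)
  gr <- afhorizon:::module_b_backward(w, fw, bce_loss(fw$logit, y)$dlogit, 3)
  eps <- 1e-6
  for (path in list(c("l1f", "W"), c("l1b", "U"), c("l2f", "W"), c("l2b", "b"),
    c("Wh1", NA), c("Wh2", NA))) {
    arr <- if (is.na(path[2])) w[[path[1]]] else w[[path[1]]][[path[2]]]
    ga <- if (is.na(path[2])) gr[[path[1]]] else gr[[path[1]]][[path[2]]]
    for (i in seq_len(min(5, length(arr)))) {
      wp <- w; wm <- w
      if (is.na(path[2])) {
        wp[[path[1]]][i] <- wp[[path[1]]][i] + eps
        wm[[path[1]]][i] <- wm[[path[1]]][i] - eps
      } else {
        wp[[path[1]]][[path[2]]][i] <- wp[[path[1]]][[path[2]]][i] + eps
        wm[[path[1]]][[path[2]]][i] <- wm[[path[1]]][[path[2]]][i] - eps
      }
      num <- (loss_of(wp) - loss_of(wm)) / (2 * eps)
      expect_equal(ga[i], num, tolerance = 1e-4)
    }
  }
})

test_that("the encoder trains to separate a constructed window contrast", {
  cfg <- encoder_config(
    input_fs = 5, window_sec = 60, widths = c(4, 4, 4, 4),
    kernel = 7, pool = c(2, 2, 2, 2), embed_dim = 16
  )
  set.seed(6)
  n <- 80
  y <- rep(0:1, each = n / 2)
  X <- t(vapply(y, function(lab) {
    tt <- seq(0, 60, length.out = cfg$input_len)
    freq <- if (lab == 1) 1.6 else 1.1 # rate contrast survives normalization
    sin(2 * pi * freq * tt) + rnorm(cfg$input_len, 0, 0.3)
  }, numeric(cfg$input_len)))
  enc <- train_module_a(X, y, cfg, seed = 2, epochs = 12, batch = 8)
  sc <- vapply(seq_len(n), function(i) encoder_window_score(X[i, ], enc), numeric(1))
  expect_gt(roc_auc(sc, y), 0.85)
  expect_length(encode_window(X[1, ], enc), 16)
})

test_that("encoding is deterministic and rejects mismatched windows", {
  cfg <- tiny_encoder()
  enc <- structure(
    list(weights = afhorizon:::encoder_init(cfg, 1), config = cfg),
    class = "af_encoder"
  )
  x <- rnorm(cfg$input_len)
  expect_identical(encode_window(x, enc), encode_window(x, enc))
  expect_length(encode_window(x, enc), cfg$embed_dim)
  expect_error(encode_window(x[-1], enc), "length")
  # resampling path: a 4x oversampled window mean-bins down to input_fs
  x8 <- rep(x, each = 4)
  expect_length(encode_window(x8, enc, fs = cfg$input_fs * 4), cfg$embed_dim)
  # default embedding width is 128
  expect_identical(encoder_config()$embed_dim, 128L)
})

test_that("module A refuses single-class training sets", {
  cfg <- tiny_encoder()
  X <- matrix(rnorm(10 * cfg$input_len), 10)
  expect_error(train_module_a(X, rep(1, 10), cfg), "single class")
})

test_that("module A training is seed-reproducible", {
  cfg <- tiny_encoder()
  set.seed(1)
  X <- matrix(rnorm(24 * cfg$input_len), 24)
  y <- rep(0:1, 12)
  e1 <- train_module_a(X, y, cfg, seed = 4, epochs = 3, batch = 6)
  e2 <- train_module_a(X, y, cfg, seed = 4, epochs = 3, batch = 6)
  expect_identical(e1$weights, e2$weights)
  expect_identical(encoder_checksum(e1), encoder_checksum(e2))
})

make_seq_data <- function(n, T_, fn, seed, effect = 1.5) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  seqs <- lapply(seq_len(n), function(i) {
    m <- matrix(rnorm(T_ * length(fn)), T_, length(fn),
      dimnames = list(NULL, fn))
    if (y[i] == 1) m[, 1] <- m[, 1] + effect
    m
  })
  demo <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  list(seqs = seqs, demo = demo, y = y)
}

test_that("AG configuration depends on demographics only", {
  set.seed(7)
  n <- 40
  demo <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  y <- as.numeric(demo[, "age"] + rnorm(n) > 0)
  m <- train_module_b(NULL, demo, y, hidden = 4, head_dim = 8, seed = 1,
    epochs = 5)
  s1 <- predict_risk(m, NULL, demo[1, ])
  s2 <- predict_risk(m, NULL, demo[1, ]) # same demographics, "different ECG"
  expect_identical(s1, s2)
  expect_true(s1 > 0 && s1 < 1)
})

test_that("sequence model accepts lengths from 1 to 144 windows", {
  d <- make_seq_data(30, 3, c("a", "b"), seed = 8)
  m <- train_module_b(d$seqs, d$demo, d$y, hidden = 4, head_dim = 6,
    seed = 2, epochs = 3)
  long <- matrix(rnorm(144 * 2), 144, 2, dimnames = list(NULL, c("a", "b")))
  p144 <- predict_risk(m, long, d$demo[1, ])
  p1 <- predict_risk(m, long, d$demo[1, ], n_windows = 1)
  expect_true(p144 > 0 && p144 < 1 && p1 > 0 && p1 < 1)
  expect_error(predict_risk(m, long[0, , drop = FALSE], d$demo[1, ]), "non-empty")
})

test_that("inference is deterministic and invariant to call batching", {
  d <- make_seq_data(30, 4, c("a", "b", "c"), seed = 9)
  m <- train_module_b(d$seqs, d$demo, d$y, hidden = 4, head_dim = 6,
    seed = 3, epochs = 3)
  one <- predict_risk(m, d$seqs[[5]], d$demo[5, ])
  many <- vapply(c(5, 5, 5), function(i) predict_risk(m, d$seqs[[i]], d$demo[i, ]),
    numeric(1))
  expect_true(all(abs(many - one) < 1e-6))
})

test_that("permuting feature-group order leaves the model unchanged", {
  # name-keyed initialization makes the model equivariant to input column
  # order, so the permuted run reproduces the same scores
  fn <- c("sdnn", "rmssd", "pac_count", "pvc_count")
  d <- make_seq_data(40, 3, fn, seed = 10)
  perm <- c(3, 4, 1, 2)
  seqs_p <- lapply(d$seqs, function(m) m[, perm, drop = FALSE])
  m1 <- train_module_b(d$seqs, d$demo, d$y, hidden = 4, head_dim = 6,
    seed = 4, epochs = 6)
  m2 <- train_module_b(seqs_p, d$demo, d$y, hidden = 4, head_dim = 6,
    seed = 4, epochs = 6)
  s1 <- vapply(seq_len(40), function(i) predict_risk(m1, d$seqs[[i]], d$demo[i, ]),
    numeric(1))
  s2 <- vapply(seq_len(40), function(i) predict_risk(m2, seqs_p[[i]], d$demo[i, ]),
    numeric(1))
  expect_lt(abs(roc_auc(s1, d$y) - roc_auc(s2, d$y)), 0.01)
  expect_lt(max(abs(s1 - s2)), 1e-6)
})

test_that("module B learns a planted sequence signal", {
  d <- make_seq_data(80, 4, c("a", "b", "c"), seed = 11, effect = 2)
  m <- train_module_b(d$seqs, d$demo, d$y, hidden = 6, head_dim = 8,
    seed = 5, epochs = 20)
  s <- vapply(seq_len(80), function(i) predict_risk(m, d$seqs[[i]], d$demo[i, ]),
    numeric(1))
  expect_gt(roc_auc(s, d$y), 0.85)
})

test_that("feature-set configurations resolve to the declared groups", {
  avail <- c(afhorizon:::HANDCRAFTED_FEATURES, paste0("emb_", 1:128))
  expect_identical(feature_set_columns(af_feature_set("AG"), avail), character(0))
  expect_true(af_feature_set("AG")$use_demo)
  dl <- af_feature_set("DL Only")
  expect_false(dl$use_demo)
  expect_identical(feature_set_columns(dl, avail), paste0("emb_", 1:128))
  all_f <- feature_set_columns(af_feature_set("All Features"), avail)
  expect_length(all_f, 22 + 128)
  expect_error(af_feature_set("bogus"))
})
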