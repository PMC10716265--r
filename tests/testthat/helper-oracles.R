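# Independent oracles used to cross-check the implementation paths.

# AUC by brute-force enumeration of all positive-negative pairs.
auc_bruteforce <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# Average precision by direct walk over the ranked list (distinct scores
# grouped), written independently of the package implementation.
ap_enumeration <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  P <- sum(y)
  ap <- 0
  prev_rec <- 0
  k <- 1
  while (k <= length(s)) {
    j <- k
    while (j < length(s) && s[j + 1] == s[k]) j <- j + 1
    tp <- sum(y[1:j])
    rec <- tp / P
    prec <- tp / j
    ap <- ap + prec * (rec - prev_rec)
    prev_rec <- rec
    k <- j + 1
  }
  ap
}

# Weighted isotonic regression by the max-min closed form:
# fit(i) = max_{j<=i} min_{k>=i ... } handled directly as
# fit(i) = max_{j<=i} min_{k>=j} wmean(y[j..k])  (O(n^3), tiny n only).
pava_maxmin <- function(y, w) {
  n <- length(y)
  wm <- function(j, k) sum(y[j:k] * w[j:k]) / sum(w[j:k])
  vapply(seq_len(n), function(i) {
    max(vapply(seq_len(i), function(j) {
      min(vapply(i:n, function(k) wm(j, k), numeric(1)))
    }, numeric(1)))
  }, numeric(1))
}

# Exhaustive-scan oracle for the AF-free interval policy: first grid start
# whose interval is AF-free with all windows valid.
interval_scan_oracle <- function(timeline, target_len) {
  fs <- timeline$fs
  len <- round(target_len * fs)
  if (len > timeline$n_samples) return(NULL)
  for (s in seq(0, timeline$n_samples - len, by = 600 * fs)) {
    if (interval_has_af_oracle(timeline$episodes, s, s + len)) next
    starts <- s + (seq_len(target_len %/% 600) - 1) * 600 * fs
    if (all(vapply(starts, function(ws) {
      window_is_valid(timeline$beats, timeline$episodes, ws, fs)$valid
    }, logical(1)))) {
      return(as.integer(s))
    }
  }
  NULL
}

interval_has_af_oracle <- function(episodes, a, b) {
  ep <- episodes[episodes$rhythm == "AF", , drop = FALSE]
  nrow(ep) > 0 && any(pmin(ep$end, b) > pmax(ep$start, a))
}

# Evenly spaced all-normal beat train covering one 10-min window.
make_sinus_beats <- function(n_beats, fs, window_sec = 600, start = 0) {
  idx <- start + round(seq(0.5, window_sec - 0.5, length.out = n_beats) * fs)
  data.frame(sample_index = as.integer(idx), beat_type = "N")
}

single_episode <- function(n_samples, rhythm_mid, a, b) {
  rows <- data.frame(
    start = c(0L, a, b), end = c(a, b, n_samples),
    rhythm = c("SINUS", rhythm_mid, "SINUS")
  )
  rows[rows$end > rows$start, ]
}
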