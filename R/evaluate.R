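# Evaluation protocol: AUC and average precision with percentile bootstrap
# confidence intervals (10,000 iterations in the reference protocol),
# paired bootstrap two-sided tests on identically sampled iterations,
# operating points at fixed sensitivity, and stratified reporting by age,
# input length and AF-burden range.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Equals the pair statistic `P(score+ > score-) + 0.5 P(tie)`, computed
#' via mid-ranks.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (both classes required).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)) # 0.75
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("AUC undefined: both classes required")
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Average precision (step-wise area under the precision-recall curve)
#'
#' Summed over distinct score thresholds: `sum over thresholds of
#' precision x delta-recall`, with no interpolation. Tied scores enter at
#' the same threshold.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (at least one positive required).
#' @return average precision in `(0, 1]`.
#' @export
#' @examples
#' average_precision(c(0.9, 0.8, 0.7), c(1, 0, 1)) # 5/6
average_precision <- function(scores, labels) {
  labels <- as.numeric(labels)
  P <- sum(labels == 1)
  if (P == 0) stop("average precision undefined without positives")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  ctp <- cumsum(y)
  k <- seq_along(y)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- ctp[last_of_tie]
  kk <- k[last_of_tie]
  prec <- tp / kk
  rec <- tp / P
  sum(prec * diff(c(0, rec)))
}

#' Operating point at a target sensitivity
#'
#' Chooses the largest score threshold whose sensitivity (with the
#' predict-positive rule `score >= threshold`) reaches at least the
#' target, and reports specificity, precision (PPV) and F1 there. When no
#' threshold achieves the target exactly, the smallest threshold with
#' sensitivity >= target is used (conservative specificity) and the
#' achieved sensitivity is returned with `exact = FALSE`.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (both classes required).
#' @param target_sens target sensitivity in (0, 1), default 0.80.
#' @return list: `threshold`, `sensitivity`, `specificity`, `precision`,
#'   `f1`, `exact`.
#' @export
operating_point_at_sensitivity <- function(scores, labels, target_sens = 0.80) {
  labels <- as.numeric(labels)
  stopifnot(target_sens > 0, target_sens < 1)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("operating point requires both classes")
  th <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(th, function(t) sum(scores >= t & labels == 1) / np, numeric(1))
  ok <- which(sens >= target_sens)
  i <- ok[1] # largest threshold reaching the target
  t <- th[i]
  tp <- sum(scores >= t & labels == 1)
  fp <- sum(scores >= t & labels == 0)
  se <- tp / np
  sp <- 1 - fp / nn
  pr <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  list(
    threshold = t, sensitivity = se, specificity = sp, precision = pr,
    f1 = f1_score(se, pr), exact = isTRUE(all.equal(se, target_sens))
  )
}

#' F1 score from sensitivity (recall) and precision
#'
#' `F1 = 2 * precision * sensitivity / (precision + sensitivity)`.
#'
#' @param sensitivity,precision values in `[0, 1]`.
#' @return F1 score.
#' @export
#' @examples
#' round(f1_score(0.80, 0.04), 2) # 0.08
f1_score <- function(sensitivity, precision) {
  2 * precision * sensitivity / (precision + sensitivity)
}

#' Pooled prevalence across strata
#'
#' Identity used in stratified reports: the overall prevalence equals the
#' recording-count-weighted mean of stratum prevalences.
#'
#' @param n recordings per stratum.
#' @param prevalence prevalence per stratum (any consistent unit).
#' @return pooled prevalence, same unit.
#' @export
pooled_prevalence <- function(n, prevalence) {
  sum(n * prevalence) / sum(n)
}

#' Percentile bootstrap confidence interval for a ranking metric
#'
#' Resamples recordings with replacement `B` times and returns the
#' percentile interval of the resampled metric. Resamples containing a
#' single class are redrawn (not skipped); the number of redraws is
#' attached as an attribute.
#'
#' @param metric_fn function `(scores, labels) -> numeric`.
#' @param scores,labels the data.
#' @param B bootstrap iterations (10,000 in the reference protocol;
#'   desk-scale default 2,000).
#' @param level confidence level.
#' @param seed integer seed.
#' @return list: `point`, `low`, `high`, `B`, with attribute `redraws`.
#' @export
bootstrap_ci <- function(metric_fn, scores, labels, B = 2000, level = 0.95,
                         seed = 1) {
  n <- length(scores)
  if (n < 10) stop("refusing to bootstrap fewer than 10 recordings")
  if (B < 100) warning("B < 100 gives unstable percentile intervals")
  labels <- as.numeric(labels)
  stats_ <- numeric(B)
  redraws <- 0L
  with_seed(af_subseed(seed, "boot"), {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2) break
        redraws <- redraws + 1L
      }
      stats_[b] <- metric_fn(scores[idx], labels[idx])
    }
  })
  a <- (1 - level) / 2
  q <- stats::quantile(stats_, c(a, 1 - a), names = FALSE, type = 7)
  structure(
    list(point = metric_fn(scores, labels), low = q[1], high = q[2], B = B),
    redraws = redraws
  )
}

#' Paired bootstrap comparison of two models on the same recordings
#'
#' Applies identical resample indices to both models' scores and
#' summarizes the distribution of the metric difference; the two-sided
#' p-value is `2 * min(frac(delta* <= 0), frac(delta* >= 0))` with
#' add-one smoothing `1/(B+1)`.
#'
#' @param metric_fn function `(scores, labels) -> numeric`.
#' @param scores_a,scores_b scores of models A and B on identical
#'   recordings.
#' @param labels 0/1 labels.
#' @param B bootstrap iterations.
#' @param seed integer seed (the same seed gives the same index stream as
#'   [bootstrap_ci()], so marginal CIs coincide).
#' @return list: `delta` (point difference A - B), `low`, `high`,
#'   `p_value`, `B`.
#' @export
paired_bootstrap_test <- function(metric_fn, scores_a, scores_b, labels,
                                  B = 2000, seed = 1) {
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(labels)) {
    stop("paired test requires scores on identical recordings")
  }
  n <- length(labels)
  labels <- as.numeric(labels)
  d <- numeric(B)
  with_seed(af_subseed(seed, "boot"), {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2) break
      }
      d[b] <- metric_fn(scores_a[idx], labels[idx]) - metric_fn(scores_b[idx], labels[idx])
    }
  })
  p <- 2 * min((sum(d <= 0) + 1) / (B + 1), (sum(d >= 0) + 1) / (B + 1))
  q <- stats::quantile(d, c(0.025, 0.975), names = FALSE, type = 7)
  list(
    delta = metric_fn(scores_a, labels) - metric_fn(scores_b, labels),
    low = q[1], high = q[2], p_value = min(p, 1), B = B
  )
}

#' Stratified evaluation report
#'
#' One row per (feature set x stratum x metric) with bootstrap CIs.
#' Strata descriptors: `overall`, age bands (`<65`, `>=65`), and AF-burden
#' ranges (`low`, `medium`, `high`). Burden strata keep all AF-negative
#' recordings in the denominator and restrict positives to the stratum
#' (negatives are shared across burden analyses).
#'
#' @param scores_by_model named list of score vectors (one per feature
#'   set), all on the same recordings.
#' @param labels 0/1 AF-positive labels.
#' @param age ages in years (optional; enables age strata).
#' @param burden per-recording AF burden fraction (optional; enables
#'   burden strata; only positives are stratified by burden).
#' @param B bootstrap iterations.
#' @param seed integer seed.
#' @return data.frame: `feature_set`, `stratum`, `n`, `prevalence`,
#'   `metric`, `point`, `ci_low`, `ci_high`.
#' @export
stratified_report <- function(scores_by_model, labels, age = NULL,
                              burden = NULL, B = 2000, seed = 1) {
  labels <- as.numeric(labels)
  strata <- list(overall = rep(TRUE, length(labels)))
  if (!is.null(age)) {
    strata[["<65"]] <- age < 65
    strata[[">=65"]] <- age >= 65
  }
  if (!is.null(burden)) {
    st <- burden_stratum(burden)
    for (g in c("low", "medium", "high")) {
      # negatives shared across burden strata; positives restricted
      strata[[paste0("burden_", g)]] <- labels == 0 | (labels == 1 & st == g)
    }
  }
  rows <- list()
  for (ms in names(scores_by_model)) {
    for (sn in names(strata)) {
      sel <- strata[[sn]]
      y <- labels[sel]
      s <- scores_by_model[[ms]][sel]
      n <- length(y)
      if (n == 0 || length(unique(y)) < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          feature_set = ms, stratum = sn, n = n, prevalence = mean(y),
          metric = c("AUC", "AP"), point = NA_real_,
          ci_low = NA_real_, ci_high = NA_real_
        )
        next
      }
      for (metric in c("AUC", "AP")) {
        fn <- if (metric == "AUC") roc_auc else average_precision
        ci <- bootstrap_ci(fn, s, y, B = B, seed = af_subseed(seed, ms, sn, metric))
        rows[[length(rows) + 1]] <- data.frame(
          feature_set = ms, stratum = sn, n = n, prevalence = mean(y),
          metric = metric, point = ci$point, ci_low = ci$low, ci_high = ci$high
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
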