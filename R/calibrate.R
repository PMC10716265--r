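# Per-age-group isotonic calibration: a monotone non-parametric map from
# raw risk scores to probabilities of observing AF in the monitoring
# window, fitted by pool-adjacent-violators on the natural-prevalence
# calibration cohort.

# Weighted pool-adjacent-violators on (x sorted increasing, y, w).
pava <- function(y, w) {
  n <- length(y)
  val <- y; wt <- w; idx_to <- seq_len(n)
  i <- 1
  # stack-based PAVA
  vals <- numeric(0); wts <- numeric(0); counts <- integer(0)
  for (i in seq_len(n)) {
    v <- y[i]; ww <- w[i]; cnt <- 1L
    while (length(vals) && vals[length(vals)] >= v) {
      v <- (vals[length(vals)] * wts[length(wts)] + v * ww) / (wts[length(wts)] + ww)
      ww <- wts[length(wts)] + ww
      cnt <- counts[length(counts)] + cnt
      vals <- vals[-length(vals)]; wts <- wts[-length(wts)]; counts <- counts[-length(counts)]
    }
    vals <- c(vals, v); wts <- c(wts, ww); counts <- c(counts, cnt)
  }
  rep(vals, counts)
}

#' Fit an isotonic calibration map for one age group
#'
#' Pools tied raw scores (weighted mean label per unique score), then runs
#' weighted pool-adjacent-violators to obtain the non-decreasing map from
#' raw score to event probability. By the isotonic normal equations, the
#' weighted mean of the fitted values equals the calibration-cohort
#' prevalence exactly. Single-class input yields a constant map at the
#' prevalence, with a warning.
#'
#' @param scores raw risk scores from the calibration split.
#' @param labels 0/1 AF-positive labels.
#' @param age_group label of the age group the map belongs to.
#' @return object of class `af_calibration_map`: `breakpoints`
#'   (increasing raw-score knots), `values` (non-decreasing probabilities),
#'   `age_group`, `n`, `prevalence`.
#' @export
fit_calibration <- function(scores, labels, age_group = "pooled") {
  stopifnot(length(scores) == length(labels), length(scores) >= 1)
  labels <- as.numeric(labels)
  prev <- mean(labels)
  if (length(unique(labels)) < 2) {
    warning("single-class calibration input; constant map at prevalence")
    return(structure(list(
      breakpoints = min(scores), values = prev,
      age_group = age_group, n = length(scores), prevalence = prev
    ), class = "af_calibration_map"))
  }
  o <- order(scores)
  s <- scores[o]; y <- labels[o]
  ux <- unique(s)
  grp <- match(s, ux)
  ybar <- as.numeric(tapply(y, grp, mean))
  w <- as.numeric(tapply(y, grp, length))
  fit <- pava(ybar, w)
  structure(list(
    breakpoints = ux, values = fit,
    age_group = age_group, n = length(scores), prevalence = prev
  ), class = "af_calibration_map")
}

#' Calibrate raw risk scores into event probabilities
#'
#' Stepwise-constant evaluation of the fitted isotonic map: a raw score
#' takes the fitted value of the largest knot not exceeding it; scores
#' outside the knot range are clipped to the boundary values. Monotone
#' (order preserving) by construction.
#'
#' @param raw raw risk scores (vectorized).
#' @param map an [fit_calibration()] object.
#' @return calibrated probabilities in `[0, 1]`.
#' @export
calibrate_score <- function(raw, map) {
  if (is.null(map)) stop("no calibration map for this age group")
  j <- findInterval(raw, map$breakpoints)
  j[j < 1] <- 1
  map$values[j]
}

#' Calibrate scores routed through per-age-group maps
#'
#' @param raw raw risk scores.
#' @param groups age-group label per score.
#' @param maps named list of [fit_calibration()] maps, one per age group.
#' @return calibrated probabilities.
#' @export
calibrate_by_group <- function(raw, groups, maps) {
  out <- numeric(length(raw))
  for (g in unique(as.character(groups))) {
    if (is.null(maps[[g]])) stop(sprintf("missing calibration map for age group '%s'", g))
    sel <- as.character(groups) == g
    out[sel] <- calibrate_score(raw[sel], maps[[g]])
  }
  out
}

#' Serialize calibration maps to JSON
#'
#' @param maps named list of calibration maps.
#' @param path output file path.
#' @export
write_calibration_json <- function(maps, path) {
  obj <- lapply(maps, function(m) {
    list(
      age_group = m$age_group, n = m$n, prevalence = m$prevalence,
      breakpoints = m$breakpoints, values = m$values
    )
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
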