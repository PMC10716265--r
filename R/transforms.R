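# Fitted per-feature normalization: exponential (1 - exp(-x)) for
# burden/rate-like features, Box-Cox + standardization for the remaining
# continuous features, passthrough for binary ones. Transforms are fitted
# on the training split only and applied unchanged everywhere else.

# Feature-role classification is deterministic (by name), not by a
# distribution test: burden/rate features are exponential-family by role.
BURDEN_FEATURES <- c(
  "svt_burden", "avb_burden", "artifact_frac",
  "pac_count", "pvc_count", "pac_per_min", "pvc_per_min"
)

# Box-Cox transform of a positive vector.
boxcox_apply <- function(x, lambda) {
  if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
}

# Profile log-likelihood estimate of the Box-Cox exponent (normality
# target), maximized over [-2, 2].
boxcox_lambda_mle <- function(x) {
  n <- length(x)
  slx <- sum(log(x))
  nll <- function(l) {
    y <- boxcox_apply(x, l)
    v <- stats::var(y) * (n - 1) / n
    0.5 * n * log(v) - (l - 1) * slx
  }
  stats::optimize(nll, c(-2, 2))$minimum
}

#' Fit per-feature normalization transforms on the training split
#'
#' Burden- and rate-like features (rhythm burdens, ectopic counts/rates)
#' get the exponential transform `y = 1 - exp(-(x - offset)/scale)` with
#' `offset` the training minimum and `scale` the training mean of the
#' offset-removed values. Other continuous features get a Box-Cox
#' transform (shift to positivity, exponent by maximum likelihood)
#' followed by standardization to zero mean / unit variance on the
#' training split. Binary features (sex) pass through as 0/1. Embedding
#' features are standardized only (a fixed Box-Cox exponent of 1, i.e. an
#' affine map). Zero-variance features fall back to passthrough with a
#' warning.
#'
#' @param train data.frame or matrix of training-split feature values
#'   (one column per feature).
#' @param passthrough character vector of feature names to pass through
#'   unchanged (default `"sex"`).
#' @param standardize_only character vector of features that get
#'   standardization without a fitted exponent (default: names starting
#'   with `"emb_"`).
#' @return list of class `af_feature_transforms`, one entry per feature
#'   with fields `kind` (`BOXCOX`, `EXPONENTIAL`, `PASSTHROUGH`),
#'   `offset`, `scale`, `lambda`, `shift`, `center`, `sd`.
#' @export
fit_transforms <- function(train, passthrough = "sex",
                           standardize_only = grep("^emb_", colnames(train), value = TRUE)) {
  train <- as.data.frame(train)
  out <- list()
  for (f in colnames(train)) {
    x <- train[[f]]
    if (f %in% passthrough) {
      out[[f]] <- list(kind = "PASSTHROUGH")
      next
    }
    if (stats::sd(x) == 0 || all(x == x[1])) {
      # constant embedding channels (dead ReLU units) are expected and
      # pass through silently; constant hand-crafted features are flagged
      if (!f %in% standardize_only) {
        warning(sprintf("feature '%s' has zero variance on the training split; passthrough", f))
      }
      out[[f]] <- list(kind = "PASSTHROUGH")
      next
    }
    if (f %in% BURDEN_FEATURES) {
      offset <- min(x)
      scale <- mean(x - offset)
      if (scale <= 0) {
        warning(sprintf("feature '%s' degenerate after offset removal; passthrough", f))
        out[[f]] <- list(kind = "PASSTHROUGH")
        next
      }
      out[[f]] <- list(kind = "EXPONENTIAL", offset = offset, scale = scale)
      next
    }
    shift <- if (min(x) > 0) 0 else -min(x) + 0.001 * (max(x) - min(x) + 1)
    lambda <- if (f %in% standardize_only) 1 else boxcox_lambda_mle(x + shift)
    y <- boxcox_apply(x + shift, lambda)
    out[[f]] <- list(
      kind = "BOXCOX", shift = shift, lambda = lambda,
      center = mean(y), sd = stats::sd(y)
    )
  }
  structure(out, class = "af_feature_transforms")
}

#' Apply fitted normalization transforms to a feature table
#'
#' Deterministic. `EXPONENTIAL`: `y = 1 - exp(-(x - offset)/scale)`
#' (strictly increasing, bounded above by 1). `BOXCOX`:
#' `((x + shift)^lambda - 1)/lambda` (log when `lambda = 0`), then
#' standardize with the training mean/sd. Values with `x + shift <= 0`
#' under Box-Cox are clamped to the smallest representable positive value
#' with a warning.
#'
#' @param features data.frame or matrix with the fitted features as columns.
#' @param transforms an [fit_transforms()] object.
#' @return data.frame of transformed features (same shape).
#' @export
apply_transforms <- function(features, transforms) {
  features <- as.data.frame(features)
  out <- features
  for (f in colnames(features)) {
    tr <- transforms[[f]]
    if (is.null(tr)) stop(sprintf("no fitted transform for feature '%s'", f))
    x <- features[[f]]
    out[[f]] <- switch(tr$kind,
      PASSTHROUGH = x,
      EXPONENTIAL = 1 - exp(-(x - tr$offset) / tr$scale),
      BOXCOX = {
        xs <- x + tr$shift
        # lambda = 1 is an affine map: defined for any input, no clamping
        if (any(xs <= 0) && tr$lambda != 1) {
          warning(sprintf("feature '%s': %d value(s) clamped to positive under Box-Cox",
            f, sum(xs <= 0)))
          xs[xs <= 0] <- .Machine$double.xmin
        }
        (boxcox_apply(xs, tr$lambda) - tr$center) / tr$sd
      }
    )
  }
  out
}

#' Invert the linear and Box-Cox parts of a fitted transform
#'
#' Recovers inputs from transformed values for `BOXCOX` (de-standardize,
#' inverse power, remove shift) and for the linear part of `EXPONENTIAL`
#' (given `y`, returns `offset - scale * log(1 - y)`). Round-trips to
#' within 1e-9 relative error.
#'
#' @param y transformed values.
#' @param tr a single-feature entry of an [fit_transforms()] object.
#' @return original-scale values.
#' @export
invert_transform <- function(y, tr) {
  switch(tr$kind,
    PASSTHROUGH = y,
    EXPONENTIAL = tr$offset - tr$scale * log(1 - y),
    BOXCOX = {
      z <- y * tr$sd + tr$center
      x <- if (abs(tr$lambda) < 1e-8) exp(z) else (z * tr$lambda + 1)^(1 / tr$lambda)
      x - tr$shift
    }
  )
}
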