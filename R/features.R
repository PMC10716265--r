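# Per-window HRV, ectopic and rhythm feature extraction. HRV metrics are
# computed on NN intervals -- intervals between successive *normal* beats,
# with any interval adjacent to an ectopic beat (PAC/PVC at either
# endpoint) discarded rather than interpolated.

#' Normal-to-normal (NN) intervals from a beat annotation stream
#'
#' Takes successive differences of beat times and keeps only intervals
#' whose both endpoints are normal beats; intervals adjacent to a PAC or
#' PVC are discarded. Ectopic beats are counted separately (see
#' [compute_rhythm_features()]).
#'
#' @param beats beat data.frame with `sample_index` (0-based) and
#'   `beat_type` (`N`, `PAC`, `PVC`), ordered by sample.
#' @param fs sampling rate, Hz.
#' @return numeric vector of NN intervals in seconds (possibly empty).
#' @export
#' @examples
#' b <- data.frame(sample_index = c(0, 100, 200, 300, 400),
#'                 beat_type = c("N", "N", "PVC", "N", "N"))
#' compute_nn_intervals(b, fs = 100) # 2 intervals: N1-N2 and N4-N5
compute_nn_intervals <- function(beats, fs) {
  if (nrow(beats) < 2) {
    return(numeric(0))
  }
  t <- beats$sample_index / fs
  d <- diff(t)
  ok <- beats$beat_type[-nrow(beats)] == "N" & beats$beat_type[-1] == "N"
  d[ok]
}

# Lomb-Scargle periodogram of an unevenly sampled series (classic form).
# Returns power density (x-units^2 per Hz) at the requested frequencies.
lomb_power <- function(t, x, freqs) {
  x <- x - mean(x)
  n <- length(x)
  pw <- vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau))
    st <- sin(w * (t - tau))
    0.5 * (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2))
  }, numeric(1))
  # normalize to a density so that band integrals approximate variance
  pw * 2 / (n / (max(t) - min(t)))
}

#' Standard short-term HRV metrics from an NN-interval series
#'
#' Computes the declared 15-metric set: mean/median NN, SDNN, RMSSD,
#' pNN50, SDSD, coefficient of variation of NN, mean/min/max heart rate,
#' a triangular-index approximation (1/128-s histogram), and Lomb-Scargle
#' spectral measures on the unevenly sampled NN series (LF power
#' 0.04-0.15 Hz, HF power 0.15-0.40 Hz, LF/HF ratio, total power
#' 0.003-0.40 Hz). Powers are reported in ms^2.
#'
#' @param nn NN intervals in seconds.
#' @param min_nn minimum number of intervals required (default 60, aligned
#'   with the sparse-R-peak validity rule).
#' @return named numeric vector of 15 metrics.
#' @export
#' @examples
#' compute_hrv(rep(1, 100))[c("sdnn", "mean_hr")] # 0 and 60
compute_hrv <- function(nn, min_nn = 60) {
  if (length(nn) < max(2, min_nn)) {
    stop(sprintf("need at least %d NN intervals (got %d)", max(2, min_nn), length(nn)))
  }
  d <- diff(nn)
  hr <- 60 / nn
  tri <- {
    h <- table(floor(nn * 128))
    length(nn) / max(h)
  }
  t_nn <- cumsum(nn)
  lf_band <- seq(0.045, 0.15, by = 0.005)
  hf_band <- seq(0.155, 0.40, by = 0.005)
  vlf_band <- seq(0.005, 0.04, by = 0.005)
  pw <- lomb_power(t_nn, nn * 1000, c(vlf_band, lf_band, hf_band))
  band_int <- function(idx, step = 0.005) sum(pw[idx]) * step
  n_vlf <- length(vlf_band)
  n_lf <- length(lf_band)
  lf <- band_int(n_vlf + seq_len(n_lf))
  hf <- band_int(n_vlf + n_lf + seq_along(hf_band))
  tp <- band_int(seq_along(pw))
  c(
    mean_nn = mean(nn), median_nn = stats::median(nn),
    sdnn = stats::sd(nn),
    rmssd = if (length(d)) sqrt(mean(d^2)) else 0,
    pnn50 = if (length(d)) mean(abs(d) > 0.05) else 0,
    sdsd = if (length(d) > 1) stats::sd(d) else 0,
    cv_nn = stats::sd(nn) / mean(nn),
    mean_hr = mean(hr), min_hr = min(hr), max_hr = max(hr),
    tri_index = tri,
    lf_power = lf, hf_power = hf,
    lf_hf_ratio = lf / max(hf, 1e-12),
    total_power = tp
  )
}

#' Rhythm-burden and ectopic-count features for one window
#'
#' Per-rhythm fraction of window time for the non-AF abnormal rhythms
#' (SVT, AVB) and artifact, plus PAC/PVC counts and per-minute rates.
#'
#' @param episodes episode partition of the recording (samples).
#' @param beats beat annotation data.frame.
#' @param start 0-based first sample of the window.
#' @param fs sampling rate, Hz.
#' @param window_sec window length in seconds (default 600).
#' @return named numeric vector: `svt_burden`, `avb_burden`,
#'   `artifact_frac`, `pac_count`, `pvc_count`, `pac_per_min`,
#'   `pvc_per_min`.
#' @export
compute_rhythm_features <- function(episodes, beats, start, fs,
                                    window_sec = WINDOW_SEC) {
  a <- start
  b <- start + window_sec * fs
  frac <- function(rh) {
    ep <- episodes[episodes$rhythm == rh, , drop = FALSE]
    if (nrow(ep) == 0) {
      return(0)
    }
    sum(pmax(0, pmin(ep$end, b) - pmax(ep$start, a))) / (b - a)
  }
  wb <- beats[beats$sample_index >= a & beats$sample_index < b, , drop = FALSE]
  pac <- sum(wb$beat_type == "PAC")
  pvc <- sum(wb$beat_type == "PVC")
  c(
    svt_burden = frac("SVT"), avb_burden = frac("AVB"),
    artifact_frac = frac("ARTIFACT"),
    pac_count = pac, pvc_count = pvc,
    pac_per_min = pac / (window_sec / 60), pvc_per_min = pvc / (window_sec / 60)
  )
}

#' All hand-crafted features for one 10-minute window
#'
#' Convenience wrapper combining [compute_nn_intervals()], [compute_hrv()]
#' and [compute_rhythm_features()] for a valid window.
#'
#' @inheritParams compute_rhythm_features
#' @param min_nn minimum NN count forwarded to [compute_hrv()].
#' @return named numeric vector of 22 features (15 HRV + 7 ectopic/rhythm).
#' @export
window_features <- function(episodes, beats, start, fs, min_nn = 60) {
  a <- start
  b <- start + WINDOW_SEC * fs
  wb <- beats[beats$sample_index >= a & beats$sample_index < b, , drop = FALSE]
  nn <- compute_nn_intervals(wb, fs)
  c(compute_hrv(nn, min_nn = min(min_nn, max(2, length(nn)))),
    compute_rhythm_features(episodes, beats, start, fs))
}
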