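# Synthetic ambulatory single-lead ECG simulator.
#
# The simulator plays the role of the proprietary monitoring data: it
# produces annotated multi-day single-lead recordings with paroxysmal AF
# episodes, atrial/ventricular ectopy, artifact segments, and a latent
# subject-level association between AF-prone status and the statistics of
# the AF-free signal (elevated PAC rate, altered HRV, subtle morphology
# shift), so that prediction from AF-free windows is learnable.
#
# Two layers:
#   * the rhythm/beat *timeline* (episodes + beat annotations), cheap to
#     generate for hours of monitoring;
#   * the *waveform*, a sum-of-Gaussians PQRST template train driven by the
#     timeline's RR process, synthesized for a whole record or lazily for
#     any sub-interval.

RHYTHM_LEVELS <- c("SINUS", "AF", "SVT", "AVB", "ARTIFACT")

#' Construct a simulation profile for one synthetic subject
#'
#' A profile bundles the subject-level parameters of the generator: baseline
#' heart rate and heart-rate variability, respiratory sinus arrhythmia
#' depth, ectopic rates, paroxysmal AF episode process, artifact process,
#' and the subtle non-AF morphology shift applied for AF-prone subjects.
#'
#' @param mean_rr mean sinus RR interval, seconds (in `[0.3, 2]`).
#' @param sdnn_target target standard deviation of sinus NN intervals, seconds.
#' @param rsa_depth fraction of NN variance carried by respiratory
#'   modulation, in `[0, 1]`.
#' @param pac_rate,pvc_rate premature atrial / ventricular contraction
#'   rates, events per hour.
#' @param af_episode_rate AF episode rate, episodes per day. A rate of 0
#'   yields AF burden exactly 0.
#' @param af_episode_duration length-2 numeric: median episode duration in
#'   seconds and log-normal log-sd.
#' @param artifact_rate artifact segments per day.
#' @param artifact_duration typical artifact duration, seconds.
#' @param svt_episode_rate,avb_episode_rate optional non-AF abnormal rhythm
#'   episode rates, episodes per day (default 0).
#' @param morphology_shift subtle P/T template perturbation in `[0, 1]`,
#'   applied in non-AF rhythm (the morphological fingerprint of AF-prone
#'   subjects).
#' @param age age in years, in `[18, 99]`.
#' @param sex `"F"` or `"M"`.
#' @return an object of class `af_sim_profile`.
#' @export
sim_profile <- function(mean_rr = 0.85, sdnn_target = 0.05, rsa_depth = 0.3,
                        pac_rate = 1, pvc_rate = 0.5,
                        af_episode_rate = 0,
                        af_episode_duration = c(median = 300, log_sd = 0.5),
                        artifact_rate = 6, artifact_duration = 60,
                        svt_episode_rate = 0, avb_episode_rate = 0,
                        morphology_shift = 0, age = 60, sex = "M") {
  stopifnot(
    mean_rr >= 0.3, mean_rr <= 2.0,
    sdnn_target >= 0, rsa_depth >= 0, rsa_depth <= 1,
    pac_rate >= 0, pvc_rate >= 0, af_episode_rate >= 0,
    artifact_rate >= 0, artifact_duration > 0,
    svt_episode_rate >= 0, avb_episode_rate >= 0,
    morphology_shift >= 0, morphology_shift <= 1,
    age >= 18, age <= 99, sex %in% c("F", "M"),
    length(af_episode_duration) == 2, all(af_episode_duration > 0)
  )
  structure(list(
    mean_rr = mean_rr, sdnn_target = sdnn_target, rsa_depth = rsa_depth,
    pac_rate = pac_rate, pvc_rate = pvc_rate,
    af_episode_rate = af_episode_rate,
    af_episode_duration = c(
      median = unname(af_episode_duration[1]),
      log_sd = unname(af_episode_duration[2])
    ),
    artifact_rate = artifact_rate, artifact_duration = artifact_duration,
    svt_episode_rate = svt_episode_rate, avb_episode_rate = avb_episode_rate,
    morphology_shift = morphology_shift, age = age, sex = sex
  ), class = "af_sim_profile")
}

# ---- interval helpers (all in seconds, half-open [start, end)) -------------

# Merge overlapping/touching intervals; input 2-col matrix (start, end).
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) {
    return(matrix(numeric(0), ncol = 2))
  }
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      if (iv[i, 1] <= out[nrow(out), 2]) {
        out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
      } else {
        out <- rbind(out, iv[i, ])
      }
    }
  }
  out
}

# Remove the parts of `iv` that overlap `occupied`; drop slivers < min_len.
subtract_intervals <- function(iv, occupied, min_len = 1) {
  if (is.null(iv) || nrow(iv) == 0) {
    return(matrix(numeric(0), ncol = 2))
  }
  if (is.null(occupied) || nrow(occupied) == 0) {
    return(iv[iv[, 2] - iv[, 1] >= min_len, , drop = FALSE])
  }
  pieces <- list()
  for (i in seq_len(nrow(iv))) {
    segs <- matrix(iv[i, ], ncol = 2)
    for (j in seq_len(nrow(occupied))) {
      nxt <- list()
      for (k in seq_len(nrow(segs))) {
        s <- segs[k, 1]; e <- segs[k, 2]
        os <- occupied[j, 1]; oe <- occupied[j, 2]
        if (oe <= s || os >= e) {
          nxt[[length(nxt) + 1]] <- c(s, e)
        } else {
          if (os > s) nxt[[length(nxt) + 1]] <- c(s, os)
          if (oe < e) nxt[[length(nxt) + 1]] <- c(oe, e)
        }
      }
      segs <- if (length(nxt)) do.call(rbind, nxt) else matrix(numeric(0), ncol = 2)
      if (nrow(segs) == 0) break
    }
    if (nrow(segs)) pieces[[length(pieces) + 1]] <- segs
  }
  out <- if (length(pieces)) do.call(rbind, pieces) else matrix(numeric(0), ncol = 2)
  out[out[, 2] - out[, 1] >= min_len, , drop = FALSE]
}

# Poisson process of episodes with log-normal durations, clipped to record.
draw_episodes <- function(rate_per_day, dur_median, dur_log_sd, duration) {
  n <- stats::rpois(1, rate_per_day * duration / 86400)
  if (n == 0) {
    return(matrix(numeric(0), ncol = 2))
  }
  start <- sort(stats::runif(n, 0, duration))
  len <- stats::rlnorm(n, meanlog = log(dur_median), sdlog = dur_log_sd)
  iv <- cbind(start, pmin(start + len, duration))
  merge_intervals(iv)
}

# ---- rhythm / beat timeline ------------------------------------------------

#' Simulate the rhythm-episode and beat-annotation timeline of a recording
#'
#' Generates the full annotation substrate of a synthetic recording without
#' synthesizing waveform samples: a rhythm-episode partition (sinus, AF,
#' optional SVT/AVB, artifact) covering the record exactly, and a
#' beat-annotation stream (N/PAC/PVC) consistent with it. Sinus RR
#' intervals follow an autocorrelated AR(1)-plus-respiration process tuned
#' to `sdnn_target`; AF episodes switch to a serially uncorrelated
#' shifted-gamma RR process (coefficient of variation ~0.25) mimicking the
#' irregularly irregular AF rhythm; artifact segments carry no beats.
#'
#' @param profile an [sim_profile()] object.
#' @param duration recording duration, seconds.
#' @param seed integer seed; identical `(profile, duration, seed)` gives
#'   bit-identical output.
#' @param fs sampling rate in Hz used to express sample indices.
#' @return a list with elements `beats` (data.frame: `time`,
#'   `sample_index` 0-based, `beat_type`), `episodes` (data.frame: `start`,
#'   `end` half-open 0-based samples, `rhythm`), `n_samples`, `fs`,
#'   `duration`, `seed`.
#' @export
simulate_rhythm_timeline <- function(profile, duration, seed, fs = 200) {
  stopifnot(inherits(profile, "af_sim_profile"), duration > 0, fs >= 100)
  n_samples <- as.integer(round(duration * fs))
  with_seed(af_subseed(seed, "timeline"), {
    # 1. episode layers, AF taking precedence, then artifacts, then SVT/AVB
    af <- draw_episodes(
      profile$af_episode_rate,
      profile$af_episode_duration[["median"]],
      profile$af_episode_duration[["log_sd"]], duration
    )
    art <- subtract_intervals(
      draw_episodes(profile$artifact_rate, profile$artifact_duration, 0.3, duration),
      af
    )
    occ <- merge_intervals(rbind(af, art))
    svt <- subtract_intervals(draw_episodes(profile$svt_episode_rate, 20, 0.3, duration), occ)
    occ <- merge_intervals(rbind(occ, svt))
    avb <- subtract_intervals(draw_episodes(profile$avb_episode_rate, 30, 0.3, duration), occ)

    labelled <- rbind(
      if (nrow(af)) cbind(af, 2) else NULL,
      if (nrow(art)) cbind(art, 5) else NULL,
      if (nrow(svt)) cbind(svt, 3) else NULL,
      if (nrow(avb)) cbind(avb, 4) else NULL
    )
    episodes <- build_partition(labelled, n_samples, fs)

    # 2. beats per contiguous episode (seconds domain)
    ep_sec <- cbind(episodes$start / fs, episodes$end / fs)
    beats <- vector("list", nrow(episodes))
    for (i in seq_len(nrow(episodes))) {
      rh <- episodes$rhythm[i]
      s <- ep_sec[i, 1]; e <- ep_sec[i, 2]
      if (rh == "ARTIFACT" || (e - s) < 0.4) next
      beats[[i]] <- switch(rh,
        SINUS = sinus_beats(profile, s, e),
        AF = af_beats(profile, s, e),
        SVT = data.frame(time = seg_times(s, e, 0.38, 0.01), beat_type = "N"),
        AVB = data.frame(
          time = seg_times(s, e, min(1.9 * profile$mean_rr, 2.4), 0.05),
          beat_type = "N"
        )
      )
    }
    beats <- do.call(rbind, beats[!vapply(beats, is.null, TRUE)])
    if (is.null(beats) || nrow(beats) == 0) {
      beats <- data.frame(time = numeric(0), beat_type = character(0))
    }
    beats <- beats[order(beats$time), , drop = FALSE]
    beats$sample_index <- as.integer(pmin(round(beats$time * fs), n_samples - 1))
    keep <- !duplicated(beats$sample_index)
    beats <- beats[keep, c("time", "sample_index", "beat_type")]
    rownames(beats) <- NULL

    list(
      beats = beats, episodes = episodes, n_samples = n_samples,
      fs = fs, duration = duration, seed = seed
    )
  })
}

# Convert labelled (start, end, code) second-intervals into an exact,
# non-overlapping sample-domain partition with SINUS filling the gaps.
build_partition <- function(labelled, n_samples, fs) {
  if (is.null(labelled) || nrow(labelled) == 0) {
    return(data.frame(start = 0L, end = n_samples, rhythm = "SINUS"))
  }
  s <- pmax(0L, pmin(as.integer(floor(labelled[, 1] * fs)), n_samples))
  e <- pmax(0L, pmin(as.integer(floor(labelled[, 2] * fs)), n_samples))
  code <- labelled[, 3]
  keep <- e > s
  s <- s[keep]; e <- e[keep]; code <- code[keep]
  o <- order(s)
  s <- s[o]; e <- e[o]; code <- code[o]
  rows <- list(); cur <- 0L
  for (i in seq_along(s)) {
    if (s[i] > cur) rows[[length(rows) + 1]] <- c(cur, s[i], 1)
    rows[[length(rows) + 1]] <- c(max(cur, s[i]), e[i], code[i])
    cur <- max(cur, e[i])
  }
  if (cur < n_samples) rows[[length(rows) + 1]] <- c(cur, n_samples, 1)
  m <- do.call(rbind, rows)
  m <- m[m[, 2] > m[, 1], , drop = FALSE]
  data.frame(
    start = as.integer(m[, 1]), end = as.integer(m[, 2]),
    rhythm = RHYTHM_LEVELS[m[, 3]]
  )
}

# Regular-ish beat train for SVT/AVB segments.
seg_times <- function(s, e, mean_rr, sd_rr) {
  m <- ceiling((e - s) / mean_rr * 1.3) + 5
  rr <- pmax(stats::rnorm(m, mean_rr, sd_rr), 0.25)
  t <- s + mean_rr / 2 + cumsum(rr) - rr[1]
  t[t < e - 0.05]
}

# Sinus beats: AR(1) NN variability + respiratory modulation, then PAC/PVC
# prematurity edits.
sinus_beats <- function(profile, s, e) {
  len <- e - s
  m <- ceiling(len / profile$mean_rr * 1.4) + 10
  phi <- 0.85
  ar_sd <- profile$sdnn_target * sqrt(1 - profile$rsa_depth^2)
  x <- stats::filter(stats::rnorm(m, 0, ar_sd * sqrt(1 - phi^2)), phi,
    method = "recursive"
  )
  rsa_amp <- profile$sdnn_target * profile$rsa_depth * sqrt(2)
  rr0 <- profile$mean_rr + as.numeric(x)
  t_prov <- cumsum(rr0)
  phase <- stats::runif(1, 0, 2 * pi)
  rr <- rr0 + rsa_amp * sin(2 * pi * 0.25 * t_prov + phase)
  rr <- pmax(rr, max(0.3 * profile$mean_rr, 0.25))
  t <- s + profile$mean_rr / 2 + cumsum(rr) - rr[1]
  keep <- t < e - 0.05
  t <- t[keep]
  nb <- length(t)
  type <- rep("N", nb)
  if (nb > 4) {
    rr_loc <- c(rr[1], diff(t))
    interior <- 2:(nb - 1)
    p_pac <- pmin(profile$pac_rate / 3600 * rr_loc[interior], 0.5)
    p_pvc <- pmin(profile$pvc_rate / 3600 * rr_loc[interior], 0.5)
    u <- stats::runif(length(interior))
    is_pac <- u < p_pac
    is_pvc <- !is_pac & (u < p_pac + p_pvc)
    idx_pac <- interior[is_pac]
    idx_pvc <- interior[is_pvc]
    for (i in sort(c(idx_pac, idx_pvc))) {
      # premature beat: shift earlier within the preceding RR interval
      shift <- 0.35 * (t[i] - t[i - 1])
      if (t[i] - shift > t[i - 1] + 0.2) t[i] <- t[i] - shift
    }
    type[idx_pac] <- "PAC"
    type[idx_pvc] <- "PVC"
  }
  o <- order(t)
  data.frame(time = t[o], beat_type = type[o])
}

# AF beats: i.i.d. shifted-gamma RR, CV ~ 0.25, slightly faster than sinus.
af_beats <- function(profile, s, e) {
  mean_af <- 0.85 * profile$mean_rr
  rr_min <- 0.35 * mean_af
  g_mean <- mean_af - rr_min
  g_sd <- 0.25 * mean_af
  shape <- (g_mean / g_sd)^2
  m <- ceiling((e - s) / mean_af * 1.5) + 10
  rr <- rr_min + stats::rgamma(m, shape = shape, scale = g_mean / shape)
  t <- s + mean_af / 2 + cumsum(rr) - rr[1]
  t <- t[t < e - 0.05]
  data.frame(time = t, beat_type = rep("N", length(t)))
}

# AF burden of an episode partition: AF samples / total samples (exact).
#' AF burden of a rhythm-episode partition
#'
#' @param episodes episode data.frame (`start`, `end` half-open samples,
#'   `rhythm`).
#' @return fraction of samples labelled AF, in `[0, 1]`.
#' @export
af_burden <- function(episodes) {
  total <- sum(episodes$end - episodes$start)
  sum((episodes$end - episodes$start)[episodes$rhythm == "AF"]) / total
}

# ---- waveform synthesis ----------------------------------------------------

# Per-beat PQRST template parameters (sum of 5 Gaussians). `m` is the
# morphology shift; AF beats lose the P wave; PVCs are wide with inverted T.
wave_params <- function(beat_type, in_af, rr_prev, m) {
  rp <- pmin(pmax(rr_prev, 0.3), 2)
  n <- length(rp)
  p_amp <- ifelse(in_af, 0, ifelse(beat_type == "PAC", 0.07, 0.12 * (1 + 0.4 * m)))
  p_off <- ifelse(beat_type == "PAC", -0.15 * rp, -0.2 * rp)
  p_w <- ifelse(beat_type == "PAC", 0.02, 0.03 * (1 + 0.6 * m))
  pvc <- beat_type == "PVC"
  list(
    amp = cbind(
      p_amp,
      ifelse(pvc, 0, -0.10),
      ifelse(pvc, 1.35, 1.10),
      ifelse(pvc, -0.50, -0.25),
      ifelse(pvc, -0.30, 0.35 * (1 - 0.35 * m))
    ),
    off = cbind(p_off, rep(-0.038, n), rep(0, n),
      ifelse(pvc, 0.06, 0.036), 0.30 * sqrt(rp)),
    wid = cbind(p_w, rep(0.012, n), ifelse(pvc, 0.05, 0.016),
      ifelse(pvc, 0.04, 0.014), 0.07 * (1 + 0.3 * m))
  )
}

#' Synthesize waveform samples for an interval of a simulated recording
#'
#' Renders the sum-of-Gaussians PQRST template train driven by the
#' timeline's beat stream over the half-open sample interval
#' `[from_sample, to_sample)`, adding baseline wander, measurement noise,
#' fibrillatory baseline oscillation within AF episodes, and high-amplitude
#' noise in artifact segments. Deterministic given the timeline seed and
#' `from_sample`.
#'
#' @param timeline output of [simulate_rhythm_timeline()].
#' @param profile the [sim_profile()] the timeline was generated from.
#' @param from_sample,to_sample half-open 0-based sample range (in
#'   timeline sampling-rate units).
#' @param out_fs output sampling rate, Hz; defaults to the timeline rate.
#'   Lower rates render the same analogue template train on a coarser
#'   grid (used to feed the window encoder directly at its input rate).
#' @return numeric vector of millivolt samples
#'   (`(to_sample - from_sample) / fs * out_fs` of them).
#' @export
synthesize_signal <- function(timeline, profile, from_sample = 0,
                              to_sample = timeline$n_samples,
                              out_fs = timeline$fs) {
  fs <- timeline$fs
  stopifnot(from_sample >= 0, to_sample <= timeline$n_samples, to_sample > from_sample)
  n <- round((to_sample - from_sample) / fs * out_fs)
  m <- profile$morphology_shift
  ph <- with_seed(
    af_subseed(timeline$seed, "phases"),
    stats::runif(3, 0, 2 * pi)
  )

  t0 <- from_sample / fs
  t1 <- to_sample / fs
  s0 <- round(t0 * out_fs) # 0-based first output sample
  beats <- timeline$beats
  sel <- beats$time >= t0 - 1.5 & beats$time <= t1 + 1.5
  beats <- beats[sel, , drop = FALSE]
  sig <- numeric(n)

  if (nrow(beats) > 0) {
    rr_prev <- c(profile$mean_rr, diff(beats$time))
    # is each beat inside an AF episode?
    ep <- timeline$episodes
    af_ep <- ep[ep$rhythm == "AF", , drop = FALSE]
    in_af <- rep(FALSE, nrow(beats))
    if (nrow(af_ep)) {
      j <- findInterval(beats$sample_index, af_ep$start)
      in_af <- j >= 1 & beats$sample_index < af_ep$end[pmax(j, 1)]
    }
    wp <- wave_params(beats$beat_type, in_af, rr_prev, m)
    for (w in 1:5) {
      centers <- beats$time + wp$off[, w]
      wid <- wp$wid[, w]
      amp <- wp$amp[, w]
      K <- max(1, ceiling(3.5 * max(wid) * out_fs))
      cidx <- round(centers * out_fs) # 0-based; unique across beats
      for (j in -K:K) {
        rel <- cidx + j - s0 + 1
        ok <- rel >= 1 & rel <= n
        if (!any(ok)) next
        tv <- (cidx[ok] + j) / out_fs
        sig[rel[ok]] <- sig[rel[ok]] +
          amp[ok] * exp(-0.5 * ((tv - centers[ok]) / wid[ok])^2)
      }
    }
  }

  tt <- (s0 + 0:(n - 1)) / out_fs
  sig <- sig + 0.04 * sin(2 * pi * 0.22 * tt + ph[1]) +
    0.03 * sin(2 * pi * 0.05 * tt + ph[2])

  ep <- timeline$episodes
  # episode bounds on the output grid, clipped to the rendered range
  orng <- function(i) {
    a <- max(round(ep$start[i] / fs * out_fs), s0)
    b <- min(round(ep$end[i] / fs * out_fs), s0 + n)
    if (b <= a) NULL else (a - s0 + 1):(b - s0)
  }
  # fibrillatory baseline oscillation within AF episodes
  for (i in which(ep$rhythm == "AF")) {
    rel <- orng(i)
    if (!is.null(rel)) sig[rel] <- sig[rel] + 0.05 * sin(2 * pi * 5.8 * tt[rel] + ph[3])
  }
  # artifact segments replace the physiological signal with high-amplitude
  # noise (labelled, not dropped)
  for (i in which(ep$rhythm == "ARTIFACT")) {
    rel <- orng(i)
    if (!is.null(rel)) sig[rel] <- 0
  }
  sig <- sig + with_seed(
    af_subseed(timeline$seed, "noise", from_sample, round(out_fs)),
    {
      noise <- stats::rnorm(n, 0, 0.02)
      for (i in which(ep$rhythm == "ARTIFACT")) {
        rel <- orng(i)
        if (!is.null(rel)) noise[rel] <- stats::rnorm(length(rel), 0, 0.8)
      }
      noise
    }
  )
  sig
}

#' Simulate a complete annotated single-lead ECG recording
#'
#' Combines [simulate_rhythm_timeline()] and [synthesize_signal()] into the
#' full recording object: waveform, beat annotations and a rhythm-episode
#' partition that covers the record exactly.
#'
#' @inheritParams simulate_rhythm_timeline
#' @param record_id record identifier string.
#' @return a list of class `af_ecg_recording` with elements `record_id`,
#'   `signal` (millivolts), `fs`, `duration`, `age`, `sex`, `beats`,
#'   `episodes`, `timeline`.
#' @export
#' @examples
#' p <- sim_profile(af_episode_rate = 0, pac_rate = 0, pvc_rate = 0,
#'                  artifact_rate = 0)
#' rec <- simulate_recording(p, duration = 600, seed = 1, fs = 100)
#' length(rec$signal) == 600 * 100
simulate_recording <- function(profile, duration, seed, fs = 200,
                               record_id = sprintf("sim-%08d", seed %% 1e8)) {
  if (!is.numeric(duration) || duration <= 0) {
    stop("duration must be positive (>= 600 s)")
  }
  if (duration < 600) stop("duration must cover at least one 10-min window (600 s)")
  if (fs < 100) stop("fs below 100 Hz undersamples the PQRST template")
  if (duration > 14 * 86400) stop("duration exceeds the 14-day wear limit")
  tl <- simulate_rhythm_timeline(profile, duration, seed, fs)
  sig <- synthesize_signal(tl, profile)
  structure(list(
    record_id = record_id, signal = sig, fs = fs, duration = duration,
    age = profile$age, sex = profile$sex,
    beats = tl$beats, episodes = tl$episodes, timeline = tl
  ), class = "af_ecg_recording")
}

# ---- cohort generation -----------------------------------------------------

# Stratum-targeted AF episode-process parameters: pick a target burden
# inside the stratum (log-uniform), an episode duration scale, and the
# matching episode rate.
stratum_af_params <- function(stratum) {
  rng <- switch(stratum,
    low = c(0.002, 0.01), medium = c(0.013, 0.09), high = c(0.11, 0.35)
  )
  b <- exp(stats::runif(1, log(rng[1]), log(rng[2])))
  d <- switch(stratum,
    low = stats::runif(1, 45, 75),
    medium = stats::runif(1, 120, 360),
    high = stats::runif(1, 400, 900)
  )
  list(burden = b, dur_median = d, rate_per_day = b * 86400 / d)
}

#' Simulate a cohort of annotated recordings with a learnable AF signature
#'
#' Draws per-subject simulation profiles and rhythm timelines for a cohort.
#' A fixed fraction of subjects is AF-prone (`round(n_subjects *
#' af_prevalence)`, deterministic); AF-prone subjects receive paroxysmal AF
#' episodes targeting the requested burden-stratum mix, an elevated PAC
#' rate, shifted NN variability and a subtle non-AF morphology shift, so
#' that AF-free windows carry a predictive signature. The manifest records
#' per-subject ground truth: latent proneness, the observed AF-positive
#' label (at least one episode longer than 30 s), realized burden and
#' burden stratum, and the persistent-AF exclusion flag (burden over 70%).
#'
#' @param n_subjects number of subjects (> 0).
#' @param af_prevalence fraction of AF-prone subjects, in `[0, 1]`.
#' @param burden_mix length-3 weights over burden strata `<1%`, `1-10%`,
#'   `>10%`; must sum to 1 (small numerical slack allowed).
#' @param seed integer master seed.
#' @param duration per-recording duration, seconds.
#' @param fs sampling rate, Hz.
#' @param effects effect sizes of the AF-prone signature: `pac_mult`
#'   (PAC-rate multiplier), `sdnn_mult` (NN-variability multiplier),
#'   `morphology_shift`.
#' @return a list of class `af_cohort`: `manifest` data.frame, `profiles`
#'   list, plus `duration`, `fs`, `seed`, `effects`.
#' @export
simulate_cohort <- function(n_subjects, af_prevalence,
                            burden_mix = c(low = 1 / 3, medium = 1 / 3, high = 1 / 3),
                            seed = 1, duration = 10800, fs = 100,
                            effects = list(pac_mult = 8, sdnn_mult = 1.4,
                                           morphology_shift = 0.3)) {
  if (n_subjects <= 0) stop("n_subjects must be positive")
  stopifnot(af_prevalence >= 0, af_prevalence <= 1)
  if (abs(sum(burden_mix) - 1) > 1e-8) stop("burden_mix weights must sum to 1")

  n_af <- round(n_subjects * af_prevalence)
  prone <- with_seed(af_subseed(seed, "prone"), {
    idx <- sample.int(n_subjects, n_af)
    seq_len(n_subjects) %in% idx
  })

  profiles <- vector("list", n_subjects)
  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    profiles[[i]] <- with_seed(af_subseed(seed, "profile", i), {
      is_af <- prone[i]
      age <- round(min(99, max(18, stats::rnorm(1, if (is_af) 70 else 60,
        if (is_af) 12 else 14
      ))))
      sex <- if (stats::runif(1) < (if (is_af) 0.55 else 0.5)) "M" else "F"
      pac <- stats::rlnorm(1, log(1), 0.5)
      sdnn <- stats::runif(1, 0.04, 0.07)
      if (is_af) {
        pac <- pac * effects$pac_mult
        sdnn <- min(sdnn * effects$sdnn_mult, 0.15)
      }
      afp <- if (is_af) {
        stratum <- sample(c("low", "medium", "high"), 1, prob = burden_mix)
        c(stratum_af_params(stratum), list(stratum = stratum))
      } else {
        list(burden = 0, dur_median = 300, rate_per_day = 0, stratum = NA_character_)
      }
      list(
        profile = sim_profile(
          mean_rr = stats::runif(1, 0.7, 1.0),
          sdnn_target = sdnn, rsa_depth = 0.3,
          pac_rate = pac, pvc_rate = stats::rlnorm(1, log(0.5), 0.5),
          af_episode_rate = afp$rate_per_day,
          af_episode_duration = c(median = afp$dur_median, log_sd = 0.4),
          artifact_rate = 6, artifact_duration = 60,
          svt_episode_rate = stats::rlnorm(1, log(2), 0.7),
          avb_episode_rate = stats::rlnorm(1, log(1), 0.7),
          morphology_shift = if (is_af) effects$morphology_shift else 0,
          age = age, sex = sex
        ),
        stratum_target = afp$stratum
      )
    })
    tl <- cohort_timeline_raw(profiles[[i]]$profile, duration, seed, i, fs)
    ep <- tl$episodes
    burden <- af_burden(ep)
    af_len <- (ep$end - ep$start)[ep$rhythm == "AF"] / fs
    af_pos <- any(af_len > 30)
    rows[[i]] <- data.frame(
      record_id = sprintf("S%05d", i), subject = i,
      age = profiles[[i]]$profile$age, sex = profiles[[i]]$profile$sex,
      af_prone = prone[i], af_positive = af_pos, af_burden = burden,
      burden_stratum = if (af_pos) burden_stratum(burden) else NA_character_,
      excluded_persistent = burden > 0.70,
      stratum_target = profiles[[i]]$stratum_target
    )
  }
  structure(list(
    manifest = do.call(rbind, rows),
    profiles = lapply(profiles, `[[`, "profile"),
    duration = duration, fs = fs, seed = seed, effects = effects
  ), class = "af_cohort")
}

cohort_timeline_raw <- function(profile, duration, seed, i, fs) {
  simulate_rhythm_timeline(profile, duration, af_subseed(seed, "rec", i), fs)
}

#' Regenerate the rhythm timeline of one cohort subject
#'
#' Timelines are not stored in the cohort object; they are regenerated
#' deterministically on demand from the master seed.
#'
#' @param cohort an [simulate_cohort()] object.
#' @param i subject index.
#' @return a timeline as returned by [simulate_rhythm_timeline()].
#' @export
cohort_timeline <- function(cohort, i) {
  cohort_timeline_raw(cohort$profiles[[i]], cohort$duration, cohort$seed, i, cohort$fs)
}

#' Map an AF burden fraction to the reporting stratum
#'
#' Strata: low (`< 1%`), medium (`1-10%`), high (`> 10%`).
#'
#' @param burden fraction in `[0, 1]` (vectorized).
#' @return character vector of `"low"`, `"medium"`, `"high"`.
#' @export
burden_stratum <- function(burden) {
  ifelse(burden < 0.01, "low", ifelse(burden <= 0.10, "medium", "high"))
}
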