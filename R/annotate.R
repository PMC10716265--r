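# Recording-level labelling, AF-free interval selection, 10-minute
# windowing with signal-quality validity rules, and cohort assembly.

WINDOW_SEC <- 600

# Structural check: episodes must tile the record exactly, half-open,
# non-overlapping. Used by every consumer of an episode partition.
validate_episodes <- function(episodes, n_samples) {
  if (nrow(episodes) == 0) stop("empty episode list")
  ep <- episodes[order(episodes$start), , drop = FALSE]
  if (any(ep$end <= ep$start)) stop("episode with start >= end")
  if (ep$start[1] != 0 || ep$end[nrow(ep)] != n_samples ||
    (nrow(ep) > 1 && any(ep$start[-1] != ep$end[-nrow(ep)]))) {
    stop("episodes must partition the record exactly (non-overlapping, covering)")
  }
  invisible(ep)
}

#' Label a recording from its rhythm-episode partition
#'
#' A recording is AF positive when it contains at least one AF episode
#' lasting more than 30 seconds. AF burden is the fraction of samples
#' labelled AF -- episodes of any length count toward burden, only
#' episodes over 30 s count toward the outcome. Recordings with burden
#' above 70% are flagged as persistent/near-persistent AF and excluded
#' from cohorts.
#'
#' @param episodes episode data.frame (`start`, `end` half-open samples,
#'   `rhythm`), forming an exact partition.
#' @param fs sampling rate, Hz.
#' @param n_samples total samples; defaults to the partition's extent.
#' @return list with `af_positive`, `af_burden`, `excluded_persistent`.
#' @export
#' @examples
#' ep <- data.frame(start = c(0L, 1000L), end = c(1000L, 86400L),
#'                  rhythm = c("AF", "SINUS"))
#' label_recording(ep, fs = 100) # 10-s AF episode: burden > 0, not positive
label_recording <- function(episodes, fs, n_samples = max(episodes$end)) {
  ep <- validate_episodes(episodes, n_samples)
  af_len <- (ep$end - ep$start)[ep$rhythm == "AF"] / fs
  burden <- sum((ep$end - ep$start)[ep$rhythm == "AF"]) / n_samples
  list(
    af_positive = any(af_len > 30),
    af_burden = burden,
    excluded_persistent = burden > 0.70
  )
}

#' Tile an interval of a recording into 10-minute analysis windows
#'
#' Windows are contiguous and non-overlapping; a trailing remainder
#' shorter than 10 minutes is dropped.
#'
#' @param n_samples total samples in the recording.
#' @param fs sampling rate, Hz.
#' @param interval_start 0-based first sample of the interval.
#' @param interval_len interval length in seconds.
#' @param record_id optional record identifier carried into the output.
#' @return data.frame with `record_id`, `window` (1-based index), `start`
#'   (0-based sample), `length` (samples).
#' @export
segment_windows <- function(n_samples, fs, interval_start = 0,
                            interval_len = n_samples / fs,
                            record_id = NA_character_) {
  win_len <- WINDOW_SEC * fs
  if (interval_start < 0 || interval_start + round(interval_len * fs) > n_samples) {
    stop("interval exceeds record bounds")
  }
  k <- floor(interval_len / WINDOW_SEC)
  if (k < 1) {
    return(data.frame(
      record_id = character(0), window = integer(0),
      start = integer(0), length = integer(0)
    ))
  }
  data.frame(
    record_id = record_id, window = seq_len(k),
    start = as.integer(interval_start + (seq_len(k) - 1) * win_len),
    length = as.integer(win_len)
  )
}

# Seconds of ARTIFACT-labelled time overlapping [a, b) (samples).
artifact_overlap <- function(episodes, a, b, fs) {
  ep <- episodes[episodes$rhythm == "ARTIFACT", , drop = FALSE]
  if (nrow(ep) == 0) {
    return(0)
  }
  sum(pmax(0, pmin(ep$end, b) - pmax(ep$start, a))) / fs
}

#' Signal-quality validity verdict for one 10-minute window
#'
#' A window is invalid when any of three independent rules fires:
#' * `LOW_HR` -- mean heart rate over the window below 20 beats/min;
#' * `ARTIFACT_EXCESS` -- more than 2 minutes of the window labelled
#'   artifact;
#' * `SPARSE_R` -- too few or too sparse R peaks for HRV computation,
#'   quantified as fewer than `min_r_peaks` usable (non-artifact) peaks or
#'   any non-artifact inter-peak gap longer than `max_gap` seconds
#'   (window edges count as gap boundaries).
#'
#' @param beats beat data.frame (`sample_index`, `beat_type`) for the whole
#'   recording (or any superset of the window).
#' @param episodes episode partition of the recording.
#' @param start 0-based first sample of the window.
#' @param fs sampling rate, Hz.
#' @param low_hr_bpm heart-rate floor, beats/min (default 20).
#' @param artifact_max_sec artifact-time ceiling, seconds (default 120).
#' @param min_r_peaks minimum usable R peaks (default 60).
#' @param max_gap maximum tolerated non-artifact inter-peak gap, seconds
#'   (default 30).
#' @return list with `valid` (logical) and `reasons` (character vector,
#'   subset of `LOW_HR`, `ARTIFACT_EXCESS`, `SPARSE_R`).
#' @export
window_is_valid <- function(beats, episodes, start, fs,
                            low_hr_bpm = 20, artifact_max_sec = 120,
                            min_r_peaks = 60, max_gap = 30) {
  a <- start
  b <- start + WINDOW_SEC * fs
  wb <- beats[beats$sample_index >= a & beats$sample_index < b, , drop = FALSE]
  reasons <- character(0)

  # 1) mean HR: all detected R peaks over the 10-min span
  if (nrow(wb) / (WINDOW_SEC / 60) < low_hr_bpm) reasons <- c(reasons, "LOW_HR")

  # 2) artifact excess: strictly more than the ceiling
  if (artifact_overlap(episodes, a, b, fs) > artifact_max_sec) {
    reasons <- c(reasons, "ARTIFACT_EXCESS")
  }

  # 3) sparse R peaks: usable (non-artifact) count and maximum non-artifact
  #    gap (edges included)
  art <- episodes[episodes$rhythm == "ARTIFACT", , drop = FALSE]
  in_art <- rep(FALSE, nrow(wb))
  if (nrow(art)) {
    j <- findInterval(wb$sample_index, art$start)
    in_art <- j >= 1 & wb$sample_index < art$end[pmax(j, 1)]
  }
  ub <- wb[!in_art, , drop = FALSE]
  sparse <- nrow(ub) < min_r_peaks
  if (!sparse) {
    pts <- c(a, ub$sample_index, b)
    for (i in seq_len(length(pts) - 1)) {
      gap_sec <- (pts[i + 1] - pts[i]) / fs
      if (gap_sec > max_gap) {
        eff <- gap_sec - artifact_overlap(episodes, pts[i], pts[i + 1], fs)
        if (eff > max_gap) {
          sparse <- TRUE
          break
        }
      }
    }
  }
  if (sparse) reasons <- c(reasons, "SPARSE_R")

  list(valid = length(reasons) == 0, reasons = reasons)
}

# Does [a, b) (samples) contain any AF-labelled sample?
interval_has_af <- function(episodes, a, b) {
  ep <- episodes[episodes$rhythm == "AF", , drop = FALSE]
  nrow(ep) > 0 && any(pmin(ep$end, b) > pmax(ep$start, a))
}

#' Select the earliest AF-free interval whose windows all pass quality rules
#'
#' Scans candidate interval starts on the 10-minute grid (from sample 0)
#' and returns the first interval of `target_len` seconds that contains no
#' AF-labelled samples and whose every 10-minute window is valid under
#' [window_is_valid()]. Returns `NULL` when the recording cannot
#' contribute at that length.
#'
#' @param timeline a recording timeline (`beats`, `episodes`, `n_samples`,
#'   `fs`), e.g. from [simulate_rhythm_timeline()].
#' @param target_len interval length in seconds (600, 3600 or 86400 in the
#'   three monitoring scenarios; any multiple of 600 is accepted).
#' @param ... validity-rule thresholds passed to [window_is_valid()].
#' @return list with `start` (0-based sample) and `windows` (the
#'   [segment_windows()] table), or `NULL`.
#' @export
select_af_free_interval <- function(timeline, target_len, ...) {
  fs <- timeline$fs
  n <- timeline$n_samples
  len_samples <- round(target_len * fs)
  if (len_samples > n) {
    return(NULL)
  }
  k <- floor(target_len / WINDOW_SEC)
  grid <- seq(0, n - len_samples, by = WINDOW_SEC * fs)
  for (s in grid) {
    if (interval_has_af(timeline$episodes, s, s + len_samples)) next
    wins <- segment_windows(n, fs, s, target_len)
    ok <- TRUE
    for (i in seq_len(k)) {
      v <- window_is_valid(timeline$beats, timeline$episodes, wins$start[i], fs, ...)
      if (!v$valid) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      return(list(start = as.integer(s), windows = wins))
    }
  }
  NULL
}

#' Age group of the risk model design
#'
#' Groups: 18-54, 55-64, 65-74, 75-84, 85-99.
#'
#' @param age age in years (vectorized).
#' @return factor with the five age-group levels.
#' @export
age_group <- function(age) {
  cut(age,
    breaks = c(17, 54, 64, 74, 84, 99),
    labels = c("18-54", "55-64", "65-74", "75-84", "85-99")
  )
}

#' Assemble subject-disjoint training, calibration and test cohorts
#'
#' Mirrors the reference cohort-construction protocol at configurable
#' scale. Within
#' each age group the training cohort is a two-stage draw: `per_group_random`
#' subjects at random, then up to `per_group_af_extra` additional
#' AF-positive subjects from the remainder (or all that are available).
#' The calibration and test cohorts are then drawn at natural prevalence
#' from the subjects not used for training. Recordings flagged as
#' persistent AF are excluded before any draw. Deterministic under `seed`.
#'
#' @param manifest cohort manifest with columns `subject`, `age`,
#'   `af_positive`, `excluded_persistent`.
#' @param per_group_random random training draw per age group.
#' @param per_group_af_extra maximum additional AF-positive training
#'   recordings per age group.
#' @param calib_per_group calibration draw per age group.
#' @param test_total total test cohort size (drawn pooled, at random).
#' @param seed integer seed.
#' @param pool_groups if `TRUE` (desk scale), treat all subjects as one
#'   group; counts then apply to the pooled cohort.
#' @return the manifest with an added `split` column (`TRAIN`,
#'   `CALIBRATION`, `TEST`, or `UNUSED`) and an `age_group` column.
#' @export
assemble_cohorts <- function(manifest, per_group_random, per_group_af_extra,
                             calib_per_group, test_total, seed,
                             pool_groups = FALSE) {
  m <- manifest[!manifest$excluded_persistent, , drop = FALSE]
  m$age_group <- if (pool_groups) factor("pooled") else age_group(m$age)
  split <- setNames(rep("UNUSED", nrow(manifest)), manifest$subject)

  with_seed(af_subseed(seed, "splits"), {
    for (g in levels(m$age_group)) {
      gi <- m$subject[m$age_group == g]
      if (length(gi) < per_group_random) {
        stop(sprintf("age group %s has %d subjects; %d requested for training",
          g, length(gi), per_group_random))
      }
      tr <- sample(gi, per_group_random)
      rest <- setdiff(gi, tr)
      af_rest <- rest[m$af_positive[match(rest, m$subject)]]
      extra <- if (length(af_rest)) {
        sample(af_rest, min(per_group_af_extra, length(af_rest)))
      } else {
        integer(0)
      }
      tr <- c(tr, extra)
      rest <- setdiff(gi, tr)
      if (length(rest) < calib_per_group) {
        stop(sprintf("age group %s: not enough subjects left for calibration", g))
      }
      cal <- sample(rest, calib_per_group)
      split[as.character(tr)] <- "TRAIN"
      split[as.character(cal)] <- "CALIBRATION"
    }
    pool <- m$subject[split[as.character(m$subject)] == "UNUSED"]
    if (length(pool) < test_total) stop("not enough subjects left for the test cohort")
    te <- sample(pool, test_total)
    split[as.character(te)] <- "TEST"
  })

  manifest$split <- unname(split[as.character(manifest$subject)])
  manifest$age_group <- age_group(manifest$age)
  manifest
}
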