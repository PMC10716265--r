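# Recording labels, windowing, validity rules, AF-free interval policy,
# cohort assembly.

fs <- 100L

test_that("the AF outcome needs an episode longer than 30 s; burden does not", {
  n <- 86400L * fs
  for (case in list(list(len = 29, pos = FALSE), list(len = 31, pos = TRUE))) {
    ep <- single_episode(n, "AF", 1000L, 1000L + as.integer(case$len * fs))
    lab <- label_recording(ep, fs)
    expect_identical(lab$af_positive, case$pos)
    expect_gt(lab$af_burden, 0)
    expect_false(lab$excluded_persistent)
  }
  # burden 0.75 -> persistent exclusion
  n <- 1000L * fs
  ep <- single_episode(n, "AF", 0L, as.integer(0.75 * n))
  lab <- label_recording(ep, fs)
  expect_true(lab$excluded_persistent)
  expect_equal(lab$af_burden, 0.75)
  # malformed partitions are structural errors
  bad <- data.frame(start = c(0L, 400L), end = c(500L, 900L), rhythm = c("SINUS", "AF"))
  expect_error(label_recording(bad, fs, n_samples = 900L), "partition")
})

test_that("10-min windows tile intervals with the floor rule", {
  n24 <- 86400L * fs
  expect_identical(nrow(segment_windows(n24, fs, 0, 86400)), 144L)
  expect_identical(nrow(segment_windows(n24, fs, 0, 3600)), 6L)
  expect_identical(nrow(segment_windows(n24, fs, 0, 600)), 1L)
  w <- segment_windows(n24, fs, 0, 25 * 60) # 25 min -> 2 windows
  expect_identical(nrow(w), 2L)
  expect_identical(w$start, c(0L, 60000L))
  expect_true(all(w$length == 600L * fs))
  # exact tiling: spans are contiguous and cover floor(len/600) windows
  w6 <- segment_windows(n24, fs, 120000L, 3600)
  expect_identical(w6$start[-1], w6$start[-6] + 60000L)
  expect_error(segment_windows(1000L, fs, 0, 3600), "bounds")
})

test_that("each validity rule fires independently and exactly", {
  n <- 600L * fs
  sinus <- data.frame(start = 0L, end = n, rhythm = "SINUS")

  # 190 beats over 10 min = 19 bpm: LOW_HR only
  v <- window_is_valid(make_sinus_beats(190, fs), sinus, 0L, fs)
  expect_false(v$valid)
  expect_identical(v$reasons, "LOW_HR")

  # clean 60-bpm window: valid
  v <- window_is_valid(make_sinus_beats(600, fs), sinus, 0L, fs)
  expect_true(v$valid)
  expect_identical(v$reasons, character(0))

  # one 121-s artifact: ARTIFACT_EXCESS only; 120 s exactly passes
  art121 <- single_episode(n, "ARTIFACT", 100L * fs, 221L * fs)
  v <- window_is_valid(make_sinus_beats(600, fs), art121, 0L, fs)
  expect_identical(v$reasons, "ARTIFACT_EXCESS")
  art120 <- single_episode(n, "ARTIFACT", 100L * fs, 220L * fs)
  expect_true(window_is_valid(make_sinus_beats(600, fs), art120, 0L, fs)$valid)

  # 59 usable R peaks (the rest buried in a 110-s artifact): SPARSE_R only
  art110 <- single_episode(n, "ARTIFACT", 200L * fs, 310L * fs)
  usable <- make_sinus_beats(59, fs)
  usable <- usable[usable$sample_index < 200L * fs | usable$sample_index >= 310L * fs, ]
  burst <- data.frame(
    sample_index = as.integer(seq(200L * fs + 10, 310L * fs - 10, length.out = 200)),
    beat_type = "N"
  )
  beats <- rbind(usable, burst)
  beats <- beats[order(beats$sample_index), ]
  v <- window_is_valid(beats, art110, 0L, fs)
  expect_identical(v$reasons, "SPARSE_R")

  # a >30-s silent gap outside artifact: SPARSE_R via the gap rule
  gappy <- make_sinus_beats(600, fs)
  gappy <- gappy[gappy$sample_index < 300L * fs | gappy$sample_index >= 340L * fs, ]
  v <- window_is_valid(gappy, sinus, 0L, fs)
  expect_identical(v$reasons, "SPARSE_R")
  # the same gap fully covered by artifact does not fire
  artgap <- single_episode(n, "ARTIFACT", 300L * fs, 340L * fs)
  expect_true(window_is_valid(gappy, artgap, 0L, fs)$valid)
})

test_that("injecting a 121-s artifact flips exactly ARTIFACT_EXCESS", {
  n <- 600L * fs
  beats <- make_sinus_beats(600, fs)
  clean <- data.frame(start = 0L, end = n, rhythm = "SINUS")
  v0 <- window_is_valid(beats, clean, 0L, fs)
  v1 <- window_is_valid(beats, single_episode(n, "ARTIFACT", 0L, 121L * fs), 0L, fs)
  expect_true(v0$valid)
  expect_identical(setdiff(v1$reasons, v0$reasons), "ARTIFACT_EXCESS")
  expect_identical(setdiff(v0$reasons, v1$reasons), character(0))
})

test_that("AF-free interval selection is earliest-first and label-exact", {
  # AF everywhere: nothing to select at any length
  n <- 7200L * fs
  tl_af <- list(
    beats = make_sinus_beats(7200, fs, 7200),
    episodes = data.frame(start = 0L, end = n, rhythm = "AF"),
    n_samples = n, fs = fs
  )
  expect_null(select_af_free_interval(tl_af, 3600))

  # fully clean record: earliest policy starts at sample 0
  tl_ok <- list(
    beats = make_sinus_beats(7200, fs, 7200),
    episodes = data.frame(start = 0L, end = n, rhythm = "SINUS"),
    n_samples = n, fs = fs
  )
  sel <- select_af_free_interval(tl_ok, 3600)
  expect_identical(sel$start, 0L)
  expect_identical(nrow(sel$windows), 6L)

  # an early >2-min artifact pushes the interval past it
  tl_art <- tl_ok
  tl_art$episodes <- single_episode(n, "ARTIFACT", 700L * fs, 830L * fs)
  sel <- select_af_free_interval(tl_art, 3600)
  expect_identical(sel$start, interval_scan_oracle(tl_art, 3600))
  expect_gt(sel$start, 0L)

  # target longer than the record: NULL
  expect_null(select_af_free_interval(tl_ok, 86400))
})

test_that("selection agrees with the exhaustive-scan oracle on simulated records", {
  for (seed in 1:6) {
    p <- sim_profile(
      af_episode_rate = 30, af_episode_duration = c(500, 0.5),
      artifact_rate = 40, pac_rate = 3
    )
    tl <- simulate_rhythm_timeline(p, 10800, seed, fs)
    got <- select_af_free_interval(tl, 3600)
    want <- interval_scan_oracle(tl, 3600)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_identical(got$start, as.integer(want))
      # re-check: the chosen interval contains zero AF samples
      expect_false(interval_has_af_oracle(tl$episodes, got$start, got$start + 3600 * fs))
    }
  }
})

make_test_manifest <- function(n, prev, seed) {
  set.seed(seed)
  data.frame(
    subject = seq_len(n), age = sample(18:99, n, replace = TRUE),
    af_positive = seq_len(n) %in% sample.int(n, round(n * prev)),
    excluded_persistent = FALSE
  )
}

test_that("training enrichment approaches 50% prevalence when AF is plentiful", {
  m <- make_test_manifest(2000, 0.10, 1)
  out <- assemble_cohorts(m,
    per_group_random = 100, per_group_af_extra = 100,
    calib_per_group = 100, test_total = 200, seed = 3, pool_groups = TRUE
  )
  tr <- out[out$split == "TRAIN", ]
  expect_identical(nrow(tr), 200L)
  expect_gt(mean(tr$af_positive), 0.45)
  # calibration/test remain near natural prevalence
  te <- out[out$split %in% c("CALIBRATION", "TEST"), ]
  expect_lt(mean(te$af_positive), 0.2)
})

test_that("cohort splits are subject-disjoint and seed-deterministic", {
  m <- make_test_manifest(1000, 0.2, 2)
  a <- assemble_cohorts(m, 100, 50, 100, 100, seed = 9, pool_groups = TRUE)
  b <- assemble_cohorts(m, 100, 50, 100, 100, seed = 9, pool_groups = TRUE)
  expect_identical(a$split, b$split)
  tr <- a$subject[a$split == "TRAIN"]
  ca <- a$subject[a$split == "CALIBRATION"]
  te <- a$subject[a$split == "TEST"]
  expect_identical(intersect(tr, ca), integer(0))
  expect_identical(intersect(tr, te), integer(0))
  expect_identical(intersect(ca, te), integer(0))
})

test_that("with no AF recordings the enrichment stage adds nothing", {
  m <- make_test_manifest(500, 0, 4)
  out <- assemble_cohorts(m, 100, 100, 100, 100, seed = 5, pool_groups = TRUE)
  expect_identical(sum(out$split == "TRAIN"), 100L)
})

test_that("persistent-AF recordings never enter any split", {
  m <- make_test_manifest(600, 0.3, 6)
  m$excluded_persistent <- seq_len(600) <= 50
  out <- assemble_cohorts(m, 100, 50, 100, 100, seed = 7, pool_groups = TRUE)
  expect_true(all(out$split[out$excluded_persistent] == "UNUSED"))
})

test_that("age groups follow the design bands", {
  expect_identical(
    as.character(age_group(c(18, 54, 55, 64, 65, 74, 75, 84, 85, 99))),
    c("18-54", "18-54", "55-64", "55-64", "65-74", "65-74",
      "75-84", "75-84", "85-99", "85-99")
  )
})
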