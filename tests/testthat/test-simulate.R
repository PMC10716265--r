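# Simulator: determinism, annotation consistency, RR-process statistics,
# burden targeting.

test_that("zero-rate profile yields a purely sinus, all-normal recording", {
  p <- sim_profile(
    af_episode_rate = 0, pac_rate = 0, pvc_rate = 0,
    artifact_rate = 0
  )
  rec <- simulate_recording(p, duration = 600, seed = 1, fs = 100)
  expect_setequal(unique(rec$episodes$rhythm), "SINUS")
  expect_setequal(unique(rec$beats$beat_type), "N")
  expect_identical(af_burden(rec$episodes), 0)
  expect_equal(length(rec$signal), 600 * 100)
})

test_that("identical (profile, duration, seed) give bit-identical output", {
  p <- sim_profile(af_episode_rate = 6, af_episode_duration = c(300, 0.5),
    pac_rate = 4, pvc_rate = 2)
  r1 <- simulate_recording(p, 600, seed = 99, fs = 100)
  r2 <- simulate_recording(p, 600, seed = 99, fs = 100)
  expect_identical(r1$signal, r2$signal)
  expect_identical(r1$beats, r2$beats)
  expect_identical(r1$episodes, r2$episodes)
  r3 <- simulate_recording(p, 600, seed = 100, fs = 100)
  expect_false(identical(r1$signal, r3$signal))
})

test_that("invalid durations and sampling rates are rejected", {
  p <- sim_profile()
  expect_error(simulate_recording(p, -10, seed = 1), "positive")
  expect_error(simulate_recording(p, 600, seed = 1, fs = 50), "100 Hz")
})

test_that("episodes partition every record exactly and burden is exact", {
  for (seed in 1:8) {
    p <- sim_profile(
      af_episode_rate = 12, af_episode_duration = c(400, 0.6),
      pac_rate = 5, pvc_rate = 2, artifact_rate = 20,
      svt_episode_rate = 10, avb_episode_rate = 10
    )
    tl <- simulate_rhythm_timeline(p, 7200, seed, 100)
    ep <- tl$episodes[order(tl$episodes$start), ]
    expect_identical(ep$start[1], 0L)
    expect_identical(ep$end[nrow(ep)], tl$n_samples)
    if (nrow(ep) > 1) {
      expect_identical(ep$start[-1], ep$end[-nrow(ep)]) # no gaps, no overlap
    }
    len <- ep$end - ep$start
    expect_identical(
      af_burden(ep),
      sum(len[ep$rhythm == "AF"]) / tl$n_samples
    )
    # beat annotations inside bounds, strictly increasing
    expect_true(all(diff(tl$beats$sample_index) > 0))
    expect_true(all(tl$beats$sample_index < tl$n_samples))
  }
})

test_that("sinus NN variability matches the target SDNN within 10%", {
  p <- sim_profile(
    af_episode_rate = 0, pac_rate = 0, pvc_rate = 0, artifact_rate = 0,
    mean_rr = 0.85, sdnn_target = 0.05
  )
  tl <- simulate_rhythm_timeline(p, 9000, seed = 3, fs = 100) # ~10,000 beats
  nn <- compute_nn_intervals(tl$beats, 100)
  expect_gt(length(nn), 9000)
  expect_lt(abs(stats::sd(nn) - 0.05) / 0.05, 0.10)
  expect_lt(abs(mean(nn) - 0.85), 0.02)
})

test_that("AF RR is serially uncorrelated while sinus RR is autocorrelated", {
  p_af <- sim_profile(af_episode_rate = 24, af_episode_duration = c(3000, 0.1))
  tl <- simulate_rhythm_timeline(p_af, 7200, seed = 5, fs = 100)
  afep <- tl$episodes[tl$episodes$rhythm == "AF", ]
  big <- afep[which.max(afep$end - afep$start), ]
  b <- tl$beats
  rr_af <- diff(b$sample_index[b$sample_index >= big$start & b$sample_index < big$end]) / 100
  expect_gt(length(rr_af), 500)
  expect_lt(stats::cor(rr_af[-1], rr_af[-length(rr_af)]), 0.2)

  p_s <- sim_profile(af_episode_rate = 0, pac_rate = 0, pvc_rate = 0, artifact_rate = 0)
  tls <- simulate_rhythm_timeline(p_s, 1200, seed = 5, fs = 100)
  rr_s <- compute_nn_intervals(tls$beats, 100)
  expect_gt(length(rr_s), 500)
  expect_gt(stats::cor(rr_s[-1], rr_s[-length(rr_s)]), 0.3)
})

test_that("mean realized AF burden tracks the episode-rate model", {
  # 4 episodes/day of median 600 s over 24 h: expected burden ~ 4*600/86400
  p <- sim_profile(af_episode_rate = 4, af_episode_duration = c(600, 0.3),
    artifact_rate = 0)
  burdens <- vapply(1:50, function(s) {
    af_burden(simulate_rhythm_timeline(p, 86400, seed = s, fs = 100)$episodes)
  }, numeric(1))
  expected <- 4 * 600 / 86400
  expect_lt(abs(mean(burdens) - expected) / expected, 0.30)
})

test_that("beat templates carry the AF and morphology-shift contrasts", {
  wp_sinus <- afhorizon:::wave_params("N", in_af = FALSE, rr_prev = 0.85, m = 0)
  wp_af <- afhorizon:::wave_params("N", in_af = TRUE, rr_prev = 0.85, m = 0)
  expect_gt(wp_sinus$amp[, 1], 0) # P wave present in sinus
  expect_identical(wp_af$amp[[1]], 0) # suppressed in AF
  # the subtle morphology shift perturbs P and T
  wp_m <- afhorizon:::wave_params("N", in_af = FALSE, rr_prev = 0.85, m = 0.3)
  expect_gt(wp_m$amp[, 1], wp_sinus$amp[, 1]) # P amplitude
  expect_gt(wp_m$wid[, 1], wp_sinus$wid[, 1]) # P width
  expect_lt(wp_m$amp[, 5], wp_sinus$amp[, 5]) # T amplitude
  # PVC template: wide QRS, no P, inverted T
  wp_v <- afhorizon:::wave_params("PVC", in_af = FALSE, rr_prev = 0.85, m = 0)
  expect_gt(wp_v$wid[, 3], wp_sinus$wid[, 3])
  expect_lt(wp_v$amp[, 5], 0)
})

test_that("cohort proneness assignment is exact and prevalence-0 is AF-free", {
  co <- simulate_cohort(60, 0.5, seed = 7, duration = 1800)
  expect_identical(sum(co$manifest$af_prone), 30L)
  co0 <- simulate_cohort(30, 0, seed = 7, duration = 1800)
  expect_true(all(co0$manifest$af_burden == 0))
  expect_false(any(co0$manifest$af_positive))
  expect_error(simulate_cohort(0, 0.5), "positive")
})

test_that("burden-stratum targeting matches the requested mix", {
  co <- simulate_cohort(300, 1.0, seed = 11)
  m <- co$manifest
  # the stratum draw itself is multinomial(300, 1/3 each): 95% interval
  tgt <- table(factor(m$stratum_target, levels = c("low", "medium", "high")))
  expect_true(all(abs(tgt - 100) < 1.96 * sqrt(300 * (1 / 3) * (2 / 3)) + 1))
  # realized burden lands in the targeted stratum for most detected-AF subjects
  pos <- m$af_positive
  conc <- mean(m$burden_stratum[pos] == m$stratum_target[pos])
  expect_gt(conc, 0.7)
  # boundary mapping of the reporting strata
  expect_identical(burden_stratum(c(0.005, 0.05, 0.2)), c("low", "medium", "high"))
})

test_that("AF-prone subjects carry the AF-free-signal signature", {
  co <- simulate_cohort(120, 0.5, seed = 13, duration = 1800)
  pr <- vapply(co$profiles, `[[`, numeric(1), "pac_rate")
  sd_t <- vapply(co$profiles, `[[`, numeric(1), "sdnn_target")
  ms <- vapply(co$profiles, `[[`, numeric(1), "morphology_shift")
  prone <- co$manifest$af_prone
  expect_gt(mean(pr[prone]) / mean(pr[!prone]), 3)
  expect_gt(mean(sd_t[prone]), mean(sd_t[!prone]))
  expect_true(all(ms[prone] > 0) && all(ms[!prone] == 0))
})

test_that("WFDB record and annotation files round-trip", {
  p <- sim_profile(af_episode_rate = 20, af_episode_duration = c(60, 0.3),
    pac_rate = 10, pvc_rate = 5)
  rec <- simulate_recording(p, 600, seed = 21, fs = 100)
  d <- withr::local_tempdir()
  write_wfdb(rec, d)
  back <- read_wfdb(d, rec$record_id)
  expect_equal(back$fs, 100)
  expect_equal(back$duration, 600)
  expect_lt(max(abs(back$signal - rec$signal)), 1 / 200 + 1e-12) # ADC quantization
  expect_identical(back$beats$sample_index, rec$beats$sample_index)
  expect_identical(back$beats$beat_type, rec$beats$beat_type)
  expect_identical(back$episodes$rhythm, rec$episodes$rhythm)
  expect_identical(back$episodes$start, rec$episodes$start)
  expect_identical(back$age, as.integer(rec$age))
  expect_identical(back$sex, rec$sex)
})
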