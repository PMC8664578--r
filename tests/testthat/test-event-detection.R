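# Low-level fixtures: single events planted on a near-silent background
# (tiny noise so the z-scoring SD is defined and thresholds engage).
single_event_recording <- function(ev, duration_s = 60, rms = 1e-3,
                                   seed = 31) {
  cfg <- psg_sim_config(duration_s = duration_s, channel_labels = "Cz",
                        noise_rms_uV = rms, seed = seed)
  out <- generate_recording(cfg, ev, rep("N3", ceiling(duration_s / 30)))
  mask <- rep(TRUE, nrow(out$rec$signal))
  list(rec = out$rec, mask = mask)
}

test_that("a planted slow-wave cycle is detected with correct properties", {
  fx <- single_event_recording(planted_event("sw", "Cz", 30, 1.0, 150))
  ev <- detect_sw_delta(fx$rec, fx$mask)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "sw")
  expect_gt(ev$intrinsic_freq_hz, 0.8)
  expect_lt(ev$intrinsic_freq_hz, 1.2)
  expect_gt(ev$amplitude_uV, 140)
  expect_lt(ev$amplitude_uV, 160)
  expect_equal(ev$trough_time_s, 30.25, tolerance = 0.05)
})

test_that("a 2.5 Hz cycle is classified delta; sub-threshold amplitudes drop", {
  fx <- single_event_recording(planted_event("delta", "Cz", 30, 2.5, 120))
  ev <- detect_sw_delta(fx$rec, fx$mask)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "delta")
  expect_equal(ev$intrinsic_freq_hz, 2.5, tolerance = 0.2)

  low <- single_event_recording(planted_event("sw", "Cz", 30, 1.0, 30))
  expect_equal(nrow(detect_sw_delta(low$rec, low$mask)), 0)
})

test_that("intrinsic frequency equals 1/(2 * peak-trough interval)", {
  # clean 2 Hz biphasic cycle: interval 0.25 s -> 2.0 Hz
  fx <- single_event_recording(planted_event("delta", "Cz", 30, 2.0, 100))
  ev <- detect_sw_delta(fx$rec, fx$mask)
  expect_equal(ev$intrinsic_freq_hz, 2.0, tolerance = 0.1)
  expect_equal(abs(ev$first_peak_time_s - ev$trough_time_s), 0.25,
               tolerance = 0.15)
})

test_that("planted spindles are detected, timed and ordered", {
  fx <- single_event_recording(
    planted_event("fast_spindle", "Cz", 30, 13.5, 60, duration_s = 1))
  ev <- detect_spindles(fx$rec, fx$mask)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "fast_spindle")
  expect_gt(ev$duration_s, 0.6)
  expect_lt(ev$duration_s, 1.4)

  short <- single_event_recording(
    planted_event("fast_spindle", "Cz", 30, 13.5, 60, duration_s = 0.3))
  expect_equal(nrow(detect_spindles(short$rec, short$mask)), 0)

  two <- single_event_recording(dplyr::bind_rows(
    planted_event("slow_spindle", "Cz", 20, 11, 60, duration_s = 1),
    planted_event("fast_spindle", "Cz", 26, 14, 60, duration_s = 1)))
  ev2 <- detect_spindles(two$rec, two$mask)
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$kind, c("slow_spindle", "fast_spindle"))
  expect_true(ev2$onset_s[1] < ev2$onset_s[2])
})

test_that("spindle intrinsic frequency estimator on canonical waveforms", {
  rate <- 500
  t <- seq(0, 1, by = 1 / rate)
  expect_equal(spindle_intrinsic_frequency(sin(2 * pi * 13 * t), rate),
               13, tolerance = 0.1)
  f11 <- spindle_intrinsic_frequency(sin(2 * pi * 11 * t), rate)
  expect_equal(f11, 11, tolerance = 0.1)
  expect_true(f11 > 9 && f11 <= 12)      # classifies as slow
  # linear chirp 12 -> 14 Hz: average frequency within the sweep
  phase <- 2 * pi * (12 * t + (14 - 12) / 2 * t^2)
  fch <- spindle_intrinsic_frequency(sin(phase), rate)
  expect_gt(fch, 12)
  expect_lt(fch, 14)
  # too few maxima
  expect_true(is.na(spindle_intrinsic_frequency(sin(2 * pi * 1 * t), rate)))
})

test_that("event summaries: densities, empty input and channel symmetry", {
  ev <- tibble::tibble(
    channel = rep(c("F3", "Cz"), each = 30),
    stage = "N2", night = "n1", kind = "sw",
    amplitude_uV = 100, duration_s = 1, intrinsic_freq_hz = 1
  )
  out <- summarize_events(ev, masked_minutes = 60)
  expect_equal(out$density_per_min, c(0.5, 0.5))
  expect_equal(out$mean_amplitude_uV, c(100, 100))
  # identical events on both channels -> identical per-channel stats
  expect_equal(out$n_events[1], out$n_events[2])

  empty <- summarize_events(ev[0, ], 60)
  expect_equal(nrow(empty), 0)

  expect_warning(summarize_events(ev, masked_minutes = 0), "zero")
})

test_that("raising the z-threshold never increases the event count", {
  night <- make_validation_night(32, counts = c(sw = 10, delta = 5),
                                 duration_s = 300)
  n_prev <- Inf
  for (zt in c(2.5, 3.5, 4.5)) {
    n <- nrow(detect_sw_delta(night$rec, night$mask,
                              detection_params(sw_zthresh = zt)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  n_prev <- Inf
  for (zt in c(2.5, 3.5, 4.5)) {
    n <- nrow(detect_spindles(night$rec, night$mask,
                              detection_params(sp_zthresh = zt)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("z-scoring is scale covariant; absolute gates are not", {
  night <- make_validation_night(33, counts = c(sw = 8), duration_s = 300)
  ev1 <- detect_sw_delta(night$rec, night$mask)
  doubled <- night$rec
  doubled$signal <- doubled$signal * 2
  ev2 <- detect_sw_delta(doubled, night$mask)
  # z-scores are scale-invariant, so every accepted trough reappears when
  # the signal is doubled (the absolute 50 uV floor can only admit more)
  expect_true(all(ev1$trough_time_s %in% ev2$trough_time_s))
  expect_gte(nrow(ev2), nrow(ev1))
  # scaling DOWN through the 50 uV floor removes every event
  shrunk <- night$rec
  shrunk$signal <- shrunk$signal * 0.3
  expect_equal(nrow(detect_sw_delta(shrunk, night$mask)), 0)
})

test_that("an all-masked-out recording yields a warning and no events", {
  rec <- make_background(quiet_recording(60, "Cz"))
  mask <- rep(FALSE, nrow(rec$signal))
  expect_warning(ev <- detect_sw_delta(rec, mask), "no samples")
  expect_equal(nrow(ev), 0)
  expect_error(detect_spindles(eeg_recording(cbind(Cz = rnorm(100)), 50),
                               rep(TRUE, 100)), "too low")
})

test_that("events are tagged with the stage of their epoch", {
  cfg <- psg_sim_config(duration_s = 120, channel_labels = "Cz",
                        noise_rms_uV = 1e-3, seed = 34)
  plan <- dplyr::bind_rows(
    planted_event("sw", "Cz", 10, 1.0, 100),   # epoch 0 -> N2
    planted_event("sw", "Cz", 70, 1.0, 100)    # epoch 2 -> N3
  )
  out <- generate_recording(cfg, plan, c("N2", "N2", "N3", "N3"))
  mask <- stage_mask(out$hyp, c("N2", "N3"), out$rec)
  ev <- detect_sw_delta(out$rec, mask, hyp = out$hyp, night = "n2")
  expect_equal(ev$stage, c("N2", "N3"))
  expect_equal(unique(ev$night), "n2")
})
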