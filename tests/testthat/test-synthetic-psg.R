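test_that("1/f background has the configured scale, slope and determinism", {
  cfg0 <- psg_sim_config(duration_s = 10, noise_rms_uV = 0, seed = 1)
  expect_true(all(make_background(cfg0)$signal == 0))

  cfg <- psg_sim_config(duration_s = 60, channel_labels = c("Fz", "Cz"),
                        seed = 7)
  a <- make_background(cfg)
  b <- make_background(cfg)
  expect_identical(a$signal, b$signal)

  rms <- sqrt(mean(a$signal[, "Cz"]^2))
  expect_equal(rms, 20, tolerance = 0.05)

  # log-log periodogram slope over 1-30 Hz (Welch-style smoothed fit)
  sp <- stats::spec.pgram(stats::ts(a$signal[, "Fz"], frequency = 500),
                          spans = 31, taper = 0, plot = FALSE)
  sel <- sp$freq >= 1 & sp$freq <= 30
  slope <- unname(stats::coef(stats::lm(log10(sp$spec[sel]) ~
                                          log10(sp$freq[sel])))[2])
  expect_gt(slope, -1.3)
  expect_lt(slope, -0.7)
})

test_that("background generation rejects invalid configurations", {
  expect_error(psg_sim_config(duration_s = -1), "positive")
  expect_error(psg_sim_config(duration_s = 10, sampling_rate = 0), "positive")
  expect_error(psg_sim_config(duration_s = 10, channel_labels = character(0)))
})

test_that("planted waveforms have the advertised geometry", {
  cfg <- quiet_recording(30, channels = c("Cz", "Fz"))
  rec <- make_background(cfg)

  # slow wave: peak-to-peak equals the configured amplitude
  sw <- plant_event(rec, planted_event("sw", "Cz", 10, 1.0, 150))
  seg <- sw$rec$signal[, "Cz"]
  expect_equal(max(seg) - min(seg), 150, tolerance = 150 * 0.01)
  expect_true(all(sw$rec$signal[, "Fz"] == 0))

  # fast spindle: mean period of local maxima matches 1/13.5 s
  sp <- plant_event(rec, planted_event("fast_spindle", "Cz", 5, 13.5, 60,
                                       duration_s = 1))
  x <- sp$rec$signal[, "Cz"]
  mx <- which(diff(sign(diff(x))) == -2) + 1
  mx <- mx[x[mx] > 0.05 * max(x)]
  expect_lt(abs(mean(diff(mx)) / 500 - 1 / 13.5), 2 / 500)

  # planted lag shows up as the cross-correlation peak
  two <- plant_event(rec, planted_event("sw", c("Cz", "Fz"), 12, 1.0, 100,
                                        lag_s = c(0, 0.2)))
  cc <- stats::ccf(two$rec$signal[, "Cz"], two$rec$signal[, "Fz"],
                   lag.max = 500, plot = FALSE)
  best_lag <- cc$lag[which.max(cc$acf)]
  expect_equal(best_lag, -0.2 * 500, tolerance = 1)
})

test_that("event windows outside the recording are rejected", {
  rec <- make_background(quiet_recording(10, "Cz"))
  expect_error(plant_event(rec, planted_event("sw", "Cz", 9.8, 1.0, 100)),
               "overruns")
  expect_error(plant_event(rec, planted_event("sw", "F9", 2, 1.0, 100)),
               "unknown channel")
})

test_that("planted_event enforces the frequency class bands", {
  expect_error(planted_event("sw", "Cz", 1, 2.0, 100), "outside")
  expect_error(planted_event("delta", "Cz", 1, 1.0, 100), "outside")
  expect_error(planted_event("slow_spindle", "Cz", 1, 13, 50), "outside")
  expect_error(planted_event("fast_spindle", "Cz", 1, 11, 50), "outside")
  # sw/delta duration is one intrinsic period
  expect_equal(planted_event("sw", "Cz", 1, 0.8, 100)$duration_s, 1.25)
})

test_that("generate_recording is background plus bookkept events", {
  cfg <- psg_sim_config(duration_s = 60, channel_labels = "Cz", seed = 3)
  empty <- generate_recording(cfg, NULL, rep("N2", 2))
  expect_identical(empty$rec$signal, make_background(cfg)$signal)
  expect_equal(nrow(empty$truth), 0)

  set.seed(1)
  plan <- plan_events(cfg, rep("N2", 2), c(sw = 5, fast_spindle = 5))
  out <- generate_recording(cfg, plan, rep("N2", 2))
  expect_equal(unname(table(out$truth$kind)["sw"]), 5)
  expect_equal(unname(table(out$truth$kind)["fast_spindle"]), 5)
  expect_equal(nrow(out$hyp), 2)

  # energy additivity: planting can only add variance
  expect_gte(stats::var(out$rec$signal[, "Cz"]),
             stats::var(empty$rec$signal[, "Cz"]))
})

test_that("overlapping same-family events trigger a separability warning", {
  cfg <- psg_sim_config(duration_s = 60, channel_labels = "Cz", seed = 4)
  plan <- dplyr::bind_rows(
    planted_event("sw", "Cz", 10, 1.0, 100),
    planted_event("sw", "Cz", 11.2, 1.0, 100)
  )
  expect_warning(generate_recording(cfg, plan, rep("N2", 2)),
                 "separability")
})

test_that("intrinsic frequency is recoverable from clean waveforms of all kinds", {
  # module-level fidelity invariant: +/- 0.2 Hz on the clean waveform
  rate <- 500
  cases <- list(c("sw", 0.9), c("sw", 1.2), c("delta", 1.8), c("delta", 3.2),
                c("slow_spindle", 9.5), c("slow_spindle", 11.7),
                c("fast_spindle", 12.3), c("fast_spindle", 15))
  for (cs in cases) {
    kind <- cs[1]; f <- as.numeric(cs[2])
    ev <- planted_event(kind, "Cz", 2,  f, 100,
                        duration_s = if (grepl("spindle", kind)) 1 else NULL)
    rec <- make_background(quiet_recording(6, "Cz"))
    x <- plant_event(rec, ev)$rec$signal[, "Cz"]
    if (grepl("spindle", kind)) {
      est <- spindle_intrinsic_frequency(x[(2 * rate):(3 * rate)], rate)
    } else {
      # detector's own estimator on the noise-free trace
      mask <- rep(TRUE, length(x))
      det <- detect_sw_delta(eeg_recording(cbind(Cz = x), rate), mask,
                             detection_params(sw_zthresh = 2))
      est <- det$intrinsic_freq_hz[1]
    }
    expect_equal(est, f, tolerance = 0.2, label = paste(kind, f))
  }
})

test_that("MST simulator calibration: noiseless improvement is exact", {
  cfg <- mst_sim_config(n_per_group = 3, base_ncs = 20, session_gain = 0,
                        gain_sd = 0, keypress_noise_ms = 0, error_rate = 0,
                        seed = 2)
  out <- generate_mst_logs(cfg)
  imp <- mst_improvement(score_mst_logs(out$logs))
  expect_true(all(imp$improvement_ncs_pct == 0))

  cfg2 <- mst_sim_config(n_per_group = 5, base_ncs = 20, session_gain = 4,
                         gain_sd = 0, keypress_noise_ms = 0, error_rate = 0,
                         seed = 2)
  out2 <- generate_mst_logs(cfg2)
  imp2 <- mst_improvement(score_mst_logs(out2$logs))
  expect_true(all(imp2$improvement_ncs_pct == 20))
  expect_true(all(out2$truth$true_improvement_pct == 20))
})

test_that("group SD multiplier scales the improvement spread", {
  cfg <- mst_sim_config(n_per_group = 200, groups = c("CC", "AA"),
                        trials_per_session = 3, base_ncs = 20,
                        session_gain = 4, gain_sd = 1.5,
                        group_sd_multiplier = c(1, 2),
                        keypress_noise_ms = 0, error_rate = 0, seed = 8)
  truth <- generate_mst_logs(cfg)$truth
  sds <- tapply(truth$true_improvement_pct, truth$group, stats::sd)
  expect_gt(sds[["AA"]] / sds[["CC"]], 1.7)
  expect_lt(sds[["AA"]] / sds[["CC"]], 2.3)
})

test_that("actigraphy generator repeats the template and flags gaps", {
  act <- generate_actigraphy(7, noise_sd = 0)
  m <- matrix(act$counts, nrow = 1440)
  expect_true(all(apply(m, 1, function(r) length(unique(r)) == 1)))

  gap <- generate_actigraphy(7, noise_sd = 0,
                             missing_spans = list(c(1440, 2880)))
  expect_equal(sum(gap$missing), 1440)
  expect_true(all(is.na(gap$counts[gap$missing])))

  n1 <- generate_actigraphy(3, noise_sd = 0.4, seed = 9)
  n2 <- generate_actigraphy(3, noise_sd = 0.4, seed = 9)
  expect_identical(n1, n2)
})
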