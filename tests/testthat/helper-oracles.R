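# Shared fixtures and independent oracles used across test files.

# A silent (zero-noise) multi-channel recording.
quiet_recording <- function(duration_s, channels = c("F3", "Cz", "O1"),
                            rate = 500) {
  psg_sim_config(duration_s = duration_s, sampling_rate = rate,
                 channel_labels = channels, noise_rms_uV = 0)
}

# Match each planted event to a detection on its own channel; returns the
# detected kind per truth row (NA = miss) and the detected frequency.
match_planted <- function(truth, sw_events, sp_events) {
  kind <- rep(NA_character_, nrow(truth))
  freq <- rep(NA_real_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    ch <- tr$channels[[1]][1]
    if (tr$kind %in% c("sw", "delta")) {
      ev <- sw_events[sw_events$channel == ch, ]
      hit <- which(abs(ev$trough_time_s -
                         (tr$onset_s + 0.25 / tr$frequency_hz)) <
                     tr$duration_s)
    } else {
      ev <- sp_events[sp_events$channel == ch, ]
      hit <- which(ev$onset_s < tr$onset_s + tr$duration_s &
                     ev$offset_s > tr$onset_s)
    }
    if (length(hit) > 0) {
      kind[i] <- ev$kind[hit[1]]
      freq[i] <- ev$intrinsic_freq_hz[hit[1]]
    }
  }
  list(kind = kind, freq = freq)
}

# Brute-force event-triggered multitaper coherogram: explicit loops over
# events and tapers, no shared code path with multitaper_coherogram()
# beyond the taper generator.
naive_coherogram <- function(ws, wt, rate, win_s = 1, step_s = 0.05,
                             k = 3, nw = 2) {
  n <- nrow(ws)
  L <- round(win_s * rate)
  step <- round(step_s * rate)
  starts <- seq(1, n - L + 1, by = step)
  tp <- dpss_tapers(L, nw, k)
  nfft <- stats::nextn(L, 2)
  nf <- nfft %/% 2 + 1
  coh <- matrix(0, length(starts), nf)
  for (p in seq_along(starts)) {
    sxy <- rep(0 + 0i, nf); sxx <- rep(0, nf); syy <- rep(0, nf)
    for (e in seq_len(ncol(ws))) {
      for (j in seq_len(k)) {
        xs <- ws[starts[p]:(starts[p] + L - 1), e] * tp[, j]
        xt <- wt[starts[p]:(starts[p] + L - 1), e] * tp[, j]
        fs <- stats::fft(c(xs, rep(0, nfft - L)))[1:nf]
        ft <- stats::fft(c(xt, rep(0, nfft - L)))[1:nf]
        sxy <- sxy + fs * Conj(ft)
        sxx <- sxx + Mod(fs)^2
        syy <- syy + Mod(ft)^2
      }
    }
    coh[p, ] <- pmin(Mod(sxy) / sqrt(sxx * syy), 1)
  }
  coh
}

# Criterion-scale synthetic night: 20 min of N2/N3 at 500 Hz with the
# standard planted-event census.
make_validation_night <- function(seed,
                                  counts = c(sw = 60, delta = 40,
                                             slow_spindle = 40,
                                             fast_spindle = 40),
                                  duration_s = 1200,
                                  noise_rms_uV = 20) {
  set.seed(seed)
  cfg <- psg_sim_config(duration_s = duration_s, seed = seed,
                        noise_rms_uV = noise_rms_uV)
  stage_blocks <- rep(c("N2", "N3"), length.out = ceiling(duration_s / 30))
  plan <- plan_events(cfg, stage_blocks, counts)
  out <- generate_recording(cfg, plan, stage_blocks)
  rec <- bandpass_fir(out$rec, 0.5, 30)
  mask <- stage_mask(out$hyp, c("N2", "N3"), rec)
  list(rec = rec, hyp = out$hyp, mask = mask, truth = out$truth)
}

# Retention of the genotype x night interaction after backward
# elimination. Under the round-wise rule the interaction is dropped at
# round 1 exactly when its full-model p >= alpha, so the (cheap) full
# fit decides most seeds and the full elimination runs only when the
# interaction survives round 1.
interaction_retained <- function(d, alpha = 0.05) {
  dd <- dplyr::mutate(d, dplyr::across(
    c("genotype", "night", "electrode", "sleep_stage", "subject"),
    as.factor))
  m <- do.call(lmerTest::lmer, list(
    formula = amplitude_uV ~ genotype + night + electrode + sleep_stage +
      genotype:night + (1 | subject),
    data = dd, REML = TRUE,
    control = lme4::lmerControl(calc.derivs = FALSE)))
  p1 <- stats::anova(m, ddf = "Satterthwaite")["genotype:night", "Pr(>F)"]
  if (is.na(p1) || p1 >= alpha) return(FALSE)
  fit <- fit_event_lmm(d, "amplitude_uV", alpha_drop = alpha,
                       marginal_means = FALSE)
  "genotype:night" %in% fit$retained
}

# Coupled two-channel slow-wave recording for coherence analyses: SW
# planted on both channels, zero lag, Gaussian onset jitter on channel 2.
sw_coherence_at_jitter <- function(jitter_s, seed, n_events = 200) {
  dur <- n_events * 4 + 8
  cfg <- psg_sim_config(duration_s = dur, channel_labels = c("F3", "O1"),
                        seed = seed)
  onsets <- seq(4, by = 4, length.out = n_events)
  plan <- dplyr::bind_rows(lapply(onsets, function(o) {
    planted_event("sw", c("F3", "O1"), o, 1.0, 80,
                  lag_s = c(0, 0), jitter_s = c(0, jitter_s))
  }))
  out <- generate_recording(cfg, plan, rep("N2", ceiling(dur / 30)))
  rec <- bandpass_fir(out$rec, 0.5, 30)
  wins <- extract_sw_windows(rec, onsets + 0.25, c("F3", "O1"))
  cg <- multitaper_coherogram(wins$windows$F3, wins$windows$O1,
                              rec$sampling_rate)
  mean_sw_coherence(cg)
}
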