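test_that("DPSS tapers are orthonormal and concentration-ordered", {
  tp <- dpss_tapers(500, 2, 3)
  expect_equal(crossprod(tp), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  # long tapers via interpolation stay orthonormal and smooth
  tp_long <- dpss_tapers(6000, 2, 3)
  expect_equal(crossprod(tp_long), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(dpss_tapers(500, 2, 6), "more tapers")
})

test_that("self-coherence is identically one", {
  set.seed(41)
  w <- matrix(rnorm(2001 * 8), 2001, 8)
  cg <- multitaper_coherogram(w, w, 500)
  expect_true(all(abs(cg$coherence - 1) < 1e-6))
})

test_that("coherogram equals a brute-force implementation on a toy instance", {
  set.seed(42)
  ws <- matrix(rnorm(2001 * 8), 2001, 8)
  wt <- matrix(rnorm(2001 * 8), 2001, 8)
  cg <- multitaper_coherogram(ws, wt, 500)
  nv <- naive_coherogram(ws, wt, 500)
  expect_lt(max(abs(cg$coherence - nv)), 1e-10)
})

test_that("independent-noise coherence sits at the multitaper bias floor", {
  set.seed(43)
  n_ev <- 100
  ws <- matrix(rnorm(2001 * n_ev), 2001, n_ev)
  wt <- matrix(rnorm(2001 * n_ev), 2001, n_ev)
  cg <- multitaper_coherogram(ws, wt, 500)
  floor_theory <- sqrt(pi / (4 * 3 * n_ev))   # E|C| for K*n averages
  expect_lt(abs(mean(cg$coherence) - floor_theory), 0.1)
  expect_true(all(cg$coherence >= 0 & cg$coherence <= 1))
})

test_that("degenerate inputs are rejected", {
  w <- matrix(rnorm(2001), 2001, 1)
  expect_error(multitaper_coherogram(w, w, 500), "at least 2 events")
  w2 <- matrix(rnorm(400 * 4), 400, 4)
  expect_error(multitaper_coherogram(w2, w2, 500, win_s = 1), "longer")
  expect_error(multitaper_coherogram(matrix(rnorm(2001 * 4), ncol = 4),
                                     matrix(rnorm(2001 * 4), ncol = 4),
                                     500, n_tapers = 5, nw = 2),
               "incompatible")
})

test_that("window extraction drops edge-clipped events and keeps shape", {
  rec <- eeg_recording(matrix(rnorm(10 * 500), ncol = 1,
                              dimnames = list(NULL, "F3")), 500)
  out <- extract_sw_windows(rec, c(1, 5))   # t=1 s clips the -2 s edge
  expect_equal(out$n_dropped, 1)
  expect_equal(dim(out$windows$F3), c(2001, 1))

  rec2 <- eeg_recording(matrix(rnorm(300 * 500), ncol = 1,
                               dimnames = list(NULL, "F3")), 500)
  times <- seq(5, by = 5.5, length.out = 51)
  out2 <- extract_sw_windows(rec2, times)
  expect_equal(ncol(out2$windows$F3), 51)
  expect_equal(nrow(out2$windows$F3), 2 * 2 * 500 + 1)

  expect_warning(extract_sw_windows(rec, numeric(0)), "no usable")
})

test_that("mean SW coherence averages exactly the stated window", {
  cg <- structure(list(
    time_s = seq(-1.5, 1.5, by = 0.05),
    freq_hz = seq(0, 20, by = 1),
    coherence = matrix(0.5, 61, 21), n_events = 10), class = "coherogram")
  expect_equal(mean_sw_coherence(cg), 0.5)
  cg$coherence[] <- 0
  cg$coherence[cg$time_s >= -0.5 & cg$time_s <= 0.5,
               cg$freq_hz >= 0.5 & cg$freq_hz <= 1.5] <- 1
  expect_equal(mean_sw_coherence(cg), 1)
  expect_error(mean_sw_coherence(cg, t_win = c(5, 6)), "intersect")
})

test_that("spectral kernel is symmetric on a shared trigger set", {
  set.seed(44)
  ws <- matrix(rnorm(2001 * 6), 2001, 6)
  wt <- matrix(rnorm(2001 * 6), 2001, 6)
  ab <- multitaper_coherogram(ws, wt, 500)
  ba <- multitaper_coherogram(wt, ws, 500)
  expect_lt(max(abs(ab$coherence - ba$coherence)), 1e-12)
})

test_that("coherence matrix: identical channels are 1, coupling beats jitter", {
  # all channels carry the same signal -> every entry 1
  set.seed(45)
  base <- rnorm(120 * 500)
  sig <- cbind(F3 = base, Cz = base, O1 = base)
  rec <- eeg_recording(sig, 500)
  ev <- tibble::tibble(channel = rep(c("F3", "Cz", "O1"), each = 3),
                       trough_time_s = rep(c(10, 40, 70), 3))
  cm <- coherence_matrix(rec, ev, t_win = c(-0.5, 0.5), f_win = c(0.5, 1.5))
  expect_true(all(abs(cm$coherence - 1) < 1e-6))

  # zero-jitter pair more coherent than 0.5 s-jitter pair
  coh0 <- sw_coherence_at_jitter(0, seed = 46, n_events = 60)
  coh5 <- sw_coherence_at_jitter(0.5, seed = 46, n_events = 60)
  expect_gt(coh0, coh5)
})

test_that("whole-epoch band coherence: identity, independence, bad band", {
  set.seed(47)
  base <- rnorm(8 * 30 * 200)
  rec_same <- eeg_recording(cbind(A = base, B = base), 200)
  mask <- rep(TRUE, length(base))
  same <- whole_epoch_band_coherence(rec_same, mask, band = c(0.5, 1.5))
  expect_true(all(abs(same$coherence - 1) < 1e-6))

  rec_ind <- eeg_recording(cbind(A = rnorm(length(base)),
                                 B = rnorm(length(base))), 200)
  ind <- whole_epoch_band_coherence(rec_ind, mask, band = c(0.5, 1.5))
  off <- ind$coherence[ind$seed != ind$target]
  expect_true(all(off < 0.3))

  expect_error(whole_epoch_band_coherence(rec_ind, mask,
                                          band = c(90, 110)), "Nyquist")
  expect_error(whole_epoch_band_coherence(rec_ind,
                                          rep(FALSE, length(base))),
               "at least 2")
})
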