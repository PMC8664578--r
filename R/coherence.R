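#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, as eigenvectors of the standard symmetric tridiagonal
#' commuting matrix. For long sequences (`n > 2048`) the tapers are
#' computed at length 2048, spline-interpolated to `n` and re-orthonormalized
#' (the classical interpolation construction); DPSS shapes converge with
#' length, so the interpolation error is far below the spectral estimation
#' variance.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (default 2).
#' @param k Number of tapers (default `2 * nw - 1`).
#' @return An `n x k` matrix; columns are unit-energy tapers, ordered by
#'   decreasing energy concentration.
#' @export
dpss_tapers <- function(n, nw = 2, k = 2 * nw - 1) {
  if (k > 2 * nw) {
    stop("requested more tapers than the bandwidth supports (k <= 2*nw)",
         call. = FALSE)
  }
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  cached <- .nremtools_cache[[key]]
  if (!is.null(cached)) return(cached)
  if (n <= 2048) {
    tapers <- dpss_direct(n, nw, k)
  } else {
    base <- dpss_direct(2048, nw, k)
    tapers <- apply(base, 2, function(v) {
      stats::spline(seq(0, 1, length.out = 2048), v,
                    xout = seq(0, 1, length.out = n))$y
    })
    tapers <- qr.Q(qr(tapers))            # re-orthonormalize
    tapers <- fix_taper_signs(tapers)
  }
  .nremtools_cache[[key]] <- tapers
  tapers
}

.nremtools_cache <- new.env(parent = emptyenv())

dpss_direct <- function(n, nw, k) {
  w <- nw / n
  i <- seq_len(n) - 1
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  e <- seq_len(n - 1) * (n - seq_len(n - 1)) / 2
  A <- diag(d)
  A[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- e
  A[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- e
  dec <- eigen(A, symmetric = TRUE)
  tapers <- dec$vectors[, seq_len(k), drop = FALSE]
  tapers <- apply(tapers, 2, function(v) v / sqrt(sum(v^2)))
  fix_taper_signs(tapers)
}

# convention: symmetric tapers have positive mean, antisymmetric tapers a
# positive initial lobe
fix_taper_signs <- function(tapers) {
  for (j in seq_len(ncol(tapers))) {
    v <- tapers[, j]
    s <- if (abs(mean(v)) > 1e-10) sign(mean(v)) else {
      sign(v[which(abs(v) > 1e-8)[1]])
    }
    tapers[, j] <- v * s
  }
  tapers
}

#' Extract slow-wave-triggered EEG windows
#'
#' Collects windows of `+/- half_width_s` seconds of (preprocessed) EEG
#' around each trigger time — in the slow-wave-triggered analysis these are
#' the SW negative-peak (trough) times on the seed electrode — on every
#' requested channel. Triggers whose window would leave the recording (or
#' the mask, if one is given) are dropped and counted.
#'
#' @param rec An [eeg_recording()].
#' @param trigger_times_s Trigger times in seconds (e.g. `trough_time_s`
#'   of detected slow waves on the seed channel).
#' @param channels Channels to extract (default all).
#' @param half_width_s Half window width in seconds (default 2).
#' @param mask Optional sample mask; windows not fully inside it are
#'   dropped.
#' @return List with `windows` (named list of samples x events matrices),
#'   `times` (kept trigger times), `n_dropped`, `half_width_s`, `rate`.
#' @export
extract_sw_windows <- function(rec, trigger_times_s,
                               channels = rec$channel_labels,
                               half_width_s = 2, mask = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  rate <- rec$sampling_rate
  hw <- round(half_width_s * rate)
  n <- nrow(rec$signal)
  centers <- round(trigger_times_s * rate) + 1L
  ok <- centers - hw >= 1L & centers + hw <= n
  if (!is.null(mask)) {
    ok <- ok & vapply(centers, function(c0) {
      c0 - hw >= 1L && c0 + hw <= n && all(mask[(c0 - hw):(c0 + hw)])
    }, logical(1))
  }
  kept <- centers[ok]
  if (length(kept) == 0) {
    warning("no usable trigger windows", call. = FALSE)
  }
  windows <- lapply(channels, function(ch) {
    vapply(kept, function(c0) rec$signal[(c0 - hw):(c0 + hw), ch],
           numeric(2 * hw + 1))
  })
  names(windows) <- channels
  list(windows = windows, times = trigger_times_s[ok],
       n_dropped = sum(!ok), half_width_s = half_width_s, rate = rate)
}

#' Event-triggered multitaper coherogram
#'
#' Slides a short analysis window (default 1 s in 50 ms steps) across a
#' pair of aligned event-window sets and, at each position, estimates the
#' magnitude coherence `|S_xy| / sqrt(S_xx S_yy)` with cross- and
#' auto-spectra averaged over DPSS tapers (default 3 tapers, NW = 2) and
#' over events. Spectra are evaluated on a power-of-two FFT grid covering
#' the analysis window.
#'
#' @param windows_seed,windows_target Samples x events matrices of aligned
#'   windows (equal dimensions), e.g. from [extract_sw_windows()].
#' @param rate Sampling rate in Hz.
#' @param win_s Sliding analysis window length in seconds.
#' @param step_s Step between window positions in seconds.
#' @param n_tapers Number of DPSS tapers.
#' @param nw Time-bandwidth product; must satisfy `n_tapers <= 2 * nw`.
#' @param t0_s Time of the alignment point (trigger) relative to window
#'   start; defaults to the window midpoint, so coherogram times are
#'   relative to the trigger.
#'
#' @return An object of class `coherogram`: list with `time_s` (window
#'   centers relative to the trigger), `freq_hz`, `coherence` (time x
#'   freq matrix in \[0, 1\]) and `n_events`.
#' @export
multitaper_coherogram <- function(windows_seed, windows_target, rate,
                                  win_s = 1.0, step_s = 0.05,
                                  n_tapers = 3, nw = 2, t0_s = NULL) {
  stopifnot(is.matrix(windows_seed), is.matrix(windows_target),
            all(dim(windows_seed) == dim(windows_target)))
  if (ncol(windows_seed) < 2) {
    stop("need at least 2 events; single-event coherence is degenerate",
         call. = FALSE)
  }
  if (n_tapers > 2 * nw) {
    stop("n_tapers incompatible with bandwidth: need n_tapers <= 2*nw",
         call. = FALSE)
  }
  n <- nrow(windows_seed)
  L <- round(win_s * rate)
  if (L > n) stop("analysis window longer than the event windows", call. = FALSE)
  step <- max(1L, round(step_s * rate))
  starts <- seq(1L, n - L + 1L, by = step)
  if (is.null(t0_s)) t0_s <- (n - 1) / (2 * rate)
  tapers <- dpss_tapers(L, nw, n_tapers)
  nfft <- stats::nextn(L, 2)
  nf <- nfft %/% 2 + 1L
  freq <- (seq_len(nf) - 1) * rate / nfft
  pad <- matrix(0, nfft - L, ncol(windows_seed))
  coh <- matrix(0, length(starts), nf)
  for (p in seq_along(starts)) {
    idx <- starts[p]:(starts[p] + L - 1L)
    xs <- windows_seed[idx, , drop = FALSE]
    xt <- windows_target[idx, , drop = FALSE]
    sxy <- complex(nf); sxx <- numeric(nf); syy <- numeric(nf)
    for (k in seq_len(n_tapers)) {
      fs <- stats::mvfft(rbind(xs * tapers[, k], pad))[seq_len(nf), , drop = FALSE]
      ft <- stats::mvfft(rbind(xt * tapers[, k], pad))[seq_len(nf), , drop = FALSE]
      sxy <- sxy + rowSums(fs * Conj(ft))
      sxx <- sxx + rowSums(Mod(fs)^2)
      syy <- syy + rowSums(Mod(ft)^2)
    }
    coh[p, ] <- pmin(Mod(sxy) / sqrt(sxx * syy), 1)
  }
  structure(
    list(time_s = (starts - 1 + (L - 1) / 2) / rate - t0_s,
         freq_hz = freq, coherence = coh,
         n_events = ncol(windows_seed),
         win_s = win_s, step_s = step_s, n_tapers = n_tapers, nw = nw),
    class = "coherogram"
  )
}

#' @export
print.coherogram <- function(x, ...) {
  cat(sprintf(
    "<coherogram> %d time bins [%.2f, %.2f] s x %d freq bins [0, %.1f] Hz, %d events\n",
    length(x$time_s), min(x$time_s), max(x$time_s), length(x$freq_hz),
    max(x$freq_hz), x$n_events))
  invisible(x)
}

#' Scalar slow-wave coherence from a coherogram
#'
#' Mean of the coherogram values whose bin centers fall inside the given
#' time and frequency windows (both closed); defaults to the
#' \[-0.5, 0.5\] s x \[0.5, 1.5\] Hz slow-wave window.
#'
#' @param cohg A `coherogram`.
#' @param t_win,f_win Closed time (s, relative to trigger) and frequency
#'   (Hz) windows.
#' @return Scalar mean coherence.
#' @export
mean_sw_coherence <- function(cohg, t_win = c(-0.5, 0.5),
                              f_win = c(0.5, 1.5)) {
  ti <- cohg$time_s >= t_win[1] & cohg$time_s <= t_win[2]
  fi <- cohg$freq_hz >= f_win[1] & cohg$freq_hz <= f_win[2]
  if (!any(ti) || !any(fi)) {
    stop("window does not intersect the coherogram axes", call. = FALSE)
  }
  mean(cohg$coherence[ti, fi])
}

#' Pairwise slow-wave-triggered coherence matrix
#'
#' For every ordered electrode pair (seed, target), triggers on the seed
#' channel's slow-wave trough times, computes the event-triggered
#' multitaper coherogram, and reduces it to the scalar slow-wave
#' coherence. Self-pairs are 1 by construction; seeds with fewer than two
#' usable events yield `NA` rows.
#'
#' @param rec An [eeg_recording()] (preprocessed).
#' @param sw_events Tibble of detected slow waves with columns `channel`
#'   and `trough_time_s` (e.g. [detect_sw_delta()] filtered to
#'   `kind == "sw"`).
#' @param channels Channels to include (default all in `rec`).
#' @param mask Optional sample mask passed to [extract_sw_windows()].
#' @param ... Passed to [multitaper_coherogram()].
#' @inheritParams mean_sw_coherence
#' @return Tibble with columns `seed`, `target`, `coherence`, `n_events`.
#' @export
coherence_matrix <- function(rec, sw_events, channels = rec$channel_labels,
                             mask = NULL, t_win = c(-0.5, 0.5),
                             f_win = c(0.5, 1.5), ...) {
  rows <- list()
  for (seed in channels) {
    times <- sw_events$trough_time_s[sw_events$channel == seed]
    wins <- if (length(times) >= 2) {
      extract_sw_windows(rec, times, channels, mask = mask)
    } else NULL
    usable <- !is.null(wins) && length(wins$times) >= 2
    if (!usable) {
      warning("seed ", seed, " has fewer than 2 usable events; row is NA",
              call. = FALSE)
    }
    for (target in channels) {
      val <- if (seed == target) {
        1
      } else if (usable) {
        cohg <- multitaper_coherogram(wins$windows[[seed]],
                                      wins$windows[[target]],
                                      rec$sampling_rate, ...)
        mean_sw_coherence(cohg, t_win, f_win)
      } else NA_real_
      rows[[length(rows) + 1L]] <- tibble::tibble(
        seed = seed, target = target, coherence = val,
        n_events = if (usable) length(wins$times) else 0L
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("coherence_matrix", class(out))
  out
}

#' Whole-epoch band coherence
#'
#' Multitaper coherence of whole (fully masked) 30-s epochs: cross- and
#' auto-spectra are averaged over tapers and epochs per channel pair and
#' the magnitude coherence is averaged over the frequency band (default
#' the 0.5-1.5 Hz slow-wave band).
#'
#' @param rec An [eeg_recording()].
#' @param mask Sample mask from [stage_mask()]; only epochs whose every
#'   sample is selected enter the estimate.
#' @param band Frequency band in Hz (closed; bin centers inside count).
#' @param channels Channels to include.
#' @param nw,n_tapers Multitaper parameters.
#' @param epoch_len_s Epoch length (30 s).
#' @return Tibble with columns `seed`, `target`, `coherence`, `n_epochs`.
#' @export
whole_epoch_band_coherence <- function(rec, mask, band = c(0.5, 1.5),
                                       channels = rec$channel_labels,
                                       nw = 2, n_tapers = 3,
                                       epoch_len_s = 30) {
  rate <- rec$sampling_rate
  if (band[2] >= rate / 2) stop("band exceeds the Nyquist frequency",
                                call. = FALSE)
  L <- round(epoch_len_s * rate)
  n_ep <- nrow(rec$signal) %/% L
  full <- which(vapply(seq_len(n_ep), function(e) {
    all(mask[((e - 1L) * L + 1L):(e * L)])
  }, logical(1)))
  if (length(full) < 2) {
    stop("need at least 2 fully masked epochs", call. = FALSE)
  }
  tapers <- dpss_tapers(L, nw, n_tapers)
  nfft <- stats::nextn(L, 2)
  nf <- nfft %/% 2 + 1L
  freq <- (seq_len(nf) - 1) * rate / nfft
  bsel <- freq >= band[1] & freq <= band[2]
  if (!any(bsel)) stop("band contains no frequency bins", call. = FALSE)
  # taper-FFT every channel's epochs once
  F <- lapply(channels, function(ch) {
    segs <- vapply(full, function(e) {
      rec$signal[((e - 1L) * L + 1L):(e * L), ch]
    }, numeric(L))
    lapply(seq_len(n_tapers), function(k) {
      stats::mvfft(rbind(segs * tapers[, k],
                         matrix(0, nfft - L, length(full))))[bsel, ,
                                                             drop = FALSE]
    })
  })
  names(F) <- channels
  rows <- list()
  for (a in channels) for (b in channels) {
    sxy <- 0; sxx <- 0; syy <- 0
    for (k in seq_len(n_tapers)) {
      fa <- F[[a]][[k]]; fb <- F[[b]][[k]]
      sxy <- sxy + rowSums(fa * Conj(fb))
      sxx <- sxx + rowSums(Mod(fa)^2)
      syy <- syy + rowSums(Mod(fb)^2)
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      seed = a, target = b,
      coherence = mean(pmin(Mod(sxy) / sqrt(sxx * syy), 1)),
      n_epochs = length(full)
    )
  }
  dplyr::bind_rows(rows)
}
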