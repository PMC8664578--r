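#' Configuration for synthetic polysomnography
#'
#' Holds the parameters of the synthetic EEG background: a 1/f^beta
#' ("pink") noise floor on each channel of a standard 9-electrode 10-20
#' montage sampled at 500 Hz, mirroring a typical PSG acquisition.
#'
#' @param duration_s Recording length in seconds.
#' @param sampling_rate Sampling rate in Hz (default 500).
#' @param channel_labels Channel names; default the 9 scalp sites
#'   F3, Fz, F4, C3, Cz, C4, Pz, O1, O2.
#' @param noise_exponent Spectral slope beta of the 1/f^beta background
#'   (default 1, i.e. pink noise).
#' @param noise_rms_uV Root-mean-square amplitude of the broadband
#'   background in uV (default 20, a typical NREM scalp EEG floor once
#'   high-amplitude events are excluded; at this floor a slow wave planted
#'   at four times the background RMS has the 80 uV peak-to-peak amplitude
#'   of a typical slow oscillation).
#' @param seed Integer seed; identical seeds give bit-identical signals.
#'
#' @return A list of class `psg_sim_config`.
#' @export
psg_sim_config <- function(duration_s,
                           sampling_rate = 500,
                           channel_labels = c("F3", "Fz", "F4", "C3", "Cz",
                                              "C4", "Pz", "O1", "O2"),
                           noise_exponent = 1,
                           noise_rms_uV = 20,
                           seed = 1L) {
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  if (sampling_rate <= 0) stop("`sampling_rate` must be positive", call. = FALSE)
  if (length(channel_labels) < 1) stop("need at least one channel", call. = FALSE)
  if (noise_rms_uV < 0) stop("`noise_rms_uV` must be >= 0", call. = FALSE)
  structure(
    list(duration_s = duration_s, sampling_rate = sampling_rate,
         channel_labels = as.character(channel_labels),
         noise_exponent = noise_exponent, noise_rms_uV = noise_rms_uV,
         seed = as.integer(seed)),
    class = "psg_sim_config"
  )
}

#' 1/f^beta background EEG
#'
#' Generates independent 1/f^beta Gaussian noise on every channel by
#' spectral shaping: white Gaussian Fourier coefficients are scaled by
#' f^(-beta/2), transformed back, demeaned, and rescaled so each channel's
#' RMS equals `noise_rms_uV` exactly.
#'
#' @param config A [psg_sim_config()].
#' @return An [eeg_recording()].
#' @export
#' @examples
#' rec <- make_background(psg_sim_config(duration_s = 10, seed = 42))
#' sd(rec$signal[, "Cz"])
make_background <- function(config) {
  stopifnot(inherits(config, "psg_sim_config"))
  n <- round(config$duration_s * config$sampling_rate)
  nch <- length(config$channel_labels)
  set.seed(config$seed)
  sig <- matrix(0, n, nch, dimnames = list(NULL, config$channel_labels))
  if (config$noise_rms_uV > 0) {
    for (ch in seq_len(nch)) {
      sig[, ch] <- one_over_f_noise(n, config$sampling_rate,
                                    config$noise_exponent,
                                    config$noise_rms_uV)
    }
  }
  eeg_recording(sig, config$sampling_rate, config$channel_labels,
                reference = "simulated (reference-free)")
}

# Single channel of 1/f^beta noise with exact RMS, by Fourier shaping.
one_over_f_noise <- function(n, rate, beta, rms) {
  freqs <- seq_len(n %/% 2) * rate / n
  amp <- freqs^(-beta / 2)
  # random spectrum: independent Gaussian real/imag parts per positive freq
  re <- stats::rnorm(length(freqs)) * amp
  im <- stats::rnorm(length(freqs)) * amp
  half <- complex(real = re, imaginary = im)
  if (n %% 2 == 0) half[length(half)] <- complex(real = re[length(re)], imaginary = 0)
  spec <- c(0, half, Conj(rev(half[seq_len(length(half) - (n %% 2 == 0))])))
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  x * (rms / sqrt(mean(x^2)))
}

#' Define an event to plant in a synthetic recording
#'
#' Describes one NREM event of a given family. Slow waves and delta waves
#' are a single biphasic cycle (negative half-wave followed by a positive
#' half-wave) whose duration is one intrinsic period; spindles are a
#' sinusoid under a raised-cosine (Hann) envelope. Amplitudes are
#' peak-to-peak throughout.
#'
#' @param kind One of `"sw"`, `"delta"`, `"slow_spindle"`, `"fast_spindle"`.
#' @param channels Channel labels the event appears on.
#' @param onset_s Nominal onset (s) on the first listed channel.
#' @param frequency_hz Intrinsic frequency (Hz). Must lie in the family's
#'   band: sw < 1.5, delta in \[1.5, 4\], slow spindle in (9, 12\], fast
#'   spindle in (12, 16\].
#' @param amplitude_uV Peak-to-peak amplitude in uV.
#' @param duration_s Event duration (s). For sw/delta this is fixed at one
#'   intrinsic period and may be omitted; for spindles it defaults to 1 s.
#' @param lag_s Per-channel onset lag (s), recycled over `channels`. The
#'   realized onset on channel j is `onset_s + lag_s[j] + N(0, jitter_s[j]^2)`.
#' @param jitter_s Per-channel lag jitter SD (s), recycled over `channels`.
#'
#' @return A one-row tibble describing the planted event.
#' @export
planted_event <- function(kind, channels, onset_s, frequency_hz,
                          amplitude_uV, duration_s = NULL,
                          lag_s = 0, jitter_s = 0) {
  kind <- match.arg(kind, c("sw", "delta", "slow_spindle", "fast_spindle"))
  ok <- switch(kind,
    sw = frequency_hz < 1.5,
    delta = frequency_hz >= 1.5 && frequency_hz <= 4,
    slow_spindle = frequency_hz > 9 && frequency_hz <= 12,
    fast_spindle = frequency_hz > 12 && frequency_hz <= 16
  )
  if (!ok) {
    stop(sprintf("frequency %.2f Hz is outside the %s band", frequency_hz,
                 kind), call. = FALSE)
  }
  if (kind %in% c("sw", "delta")) {
    duration_s <- 1 / frequency_hz
  } else if (is.null(duration_s)) {
    duration_s <- 1
  }
  if (any(jitter_s < 0)) stop("`jitter_s` must be >= 0", call. = FALSE)
  channels <- as.character(channels)
  lag_per_ch <- rep_len(lag_s, length(channels))
  jitter_per_ch <- rep_len(jitter_s, length(channels))
  tibble::tibble(
    kind = kind,
    channels = list(channels),
    onset_s = onset_s,
    duration_s = duration_s,
    amplitude_uV = amplitude_uV,
    frequency_hz = frequency_hz,
    lag_s = list(lag_per_ch),
    jitter_s = list(jitter_per_ch)
  )
}

# Clean event waveform sampled at `rate`, peak-to-peak `amp`.
event_waveform <- function(kind, frequency_hz, duration_s, amp, rate) {
  n <- round(duration_s * rate)
  t <- seq_len(n) / rate
  if (kind %in% c("sw", "delta")) {
    # one full cycle: trough first, then the positive half-wave
    -(amp / 2) * sin(2 * pi * frequency_hz * t)
  } else {
    env <- 0.5 * (1 - cos(2 * pi * (t - t[1]) / (duration_s)))
    (amp / 2) * sin(2 * pi * frequency_hz * t) * env
  }
}

#' Add a planted event to a recording
#'
#' Inserts the event waveform on every listed channel, shifting the onset
#' per channel by its lag plus Gaussian jitter, and returns the modified
#' recording together with the realized ground-truth record (per-channel
#' onsets after jitter).
#'
#' @param rec An [eeg_recording()].
#' @param ev A one-row tibble from [planted_event()].
#' @return A list with elements `rec` (modified recording) and `truth`
#'   (one-row tibble: event descriptors plus a `channel_onsets` list-column
#'   of realized onsets, named by channel).
#' @export
plant_event <- function(rec, ev) {
  stopifnot(inherits(rec, "eeg_recording"), nrow(ev) == 1)
  patch <- event_patch(dim(rec$signal)[1], colnames(rec$signal),
                       rec$sampling_rate, ev)
  for (p in patch$spans) {
    rec$signal[p$rows, p$channel] <- rec$signal[p$rows, p$channel] + p$add
  }
  truth <- ev
  truth$channel_onsets <- list(patch$onsets)
  list(rec = rec, truth = truth)
}

# realized per-channel onsets and signal patches for one event (jitter is
# drawn here, so the RNG stream advances exactly once per jittered channel)
event_patch <- function(n, labels, rate, ev) {
  chans <- ev$channels[[1]]
  missing_ch <- setdiff(chans, labels)
  if (length(missing_ch) > 0) {
    stop("unknown channel(s): ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  lags <- ev$lag_s[[1]]
  jit <- ev$jitter_s[[1]]
  wav <- event_waveform(ev$kind, ev$frequency_hz, ev$duration_s,
                        ev$amplitude_uV, rate)
  onsets <- numeric(length(chans))
  spans <- vector("list", length(chans))
  for (j in seq_along(chans)) {
    onsets[j] <- ev$onset_s + lags[j] +
      if (jit[j] > 0) stats::rnorm(1, 0, jit[j]) else 0
    i0 <- round(onsets[j] * rate) + 1L
    i1 <- i0 + length(wav) - 1L
    if (i0 < 1L || i1 > n) {
      stop(sprintf("event window [%.2f, %.2f] s overruns the recording",
                   onsets[j], onsets[j] + ev$duration_s), call. = FALSE)
    }
    spans[[j]] <- list(rows = i0:i1, channel = chans[j], add = wav)
  }
  names(onsets) <- chans
  list(spans = spans, onsets = onsets)
}

#' Generate a synthetic PSG recording with planted events
#'
#' Builds the 1/f background, plants every event of the plan, and returns
#' the recording together with its hypnogram and the ground-truth table.
#' Event jitter draws are taken after the background under the same seed,
#' so the full output is reproducible from `(config, event_plan,
#' stage_blocks)`.
#'
#' @param config A [psg_sim_config()].
#' @param event_plan Tibble of planted events (rows from
#'   [planted_event()], bound together). May be empty.
#' @param stage_blocks Character vector of stages, one per 30-s epoch,
#'   tiling `duration_s`. Defaults to all-N2.
#' @param artifact Logical per-epoch artifact flags (default none).
#'
#' @return A list with `rec` (an [eeg_recording()]), `hyp` (a
#'   [hypnogram()]) and `truth` (tibble of realized planted events).
#' @export
generate_recording <- function(config, event_plan = NULL,
                               stage_blocks = NULL, artifact = FALSE) {
  n_epochs <- ceiling(config$duration_s / 30)
  if (is.null(stage_blocks)) stage_blocks <- rep("N2", n_epochs)
  if (length(stage_blocks) != n_epochs) {
    stop("`stage_blocks` must supply one stage per 30-s epoch", call. = FALSE)
  }
  rec <- make_background(config)
  hyp <- hypnogram(stage_blocks, artifact = artifact)
  truth <- tibble::tibble()
  if (!is.null(event_plan) && nrow(event_plan) > 0) {
    warn_close_events(event_plan)
    sig <- rec$signal
    rec$signal <- NULL                  # detach so `sig` stays unshared
    rate <- rec$sampling_rate
    labels <- colnames(sig)
    n <- nrow(sig)
    onset_rows <- vector("list", nrow(event_plan))
    for (i in seq_len(nrow(event_plan))) {
      patch <- event_patch(n, labels, rate, event_plan[i, ])
      for (p in patch$spans) {
        sig[p$rows, p$channel] <- sig[p$rows, p$channel] + p$add
      }
      onset_rows[[i]] <- patch$onsets
    }
    rec$signal <- sig
    truth <- event_plan
    truth$channel_onsets <- onset_rows
    truth$event_id <- seq_len(nrow(truth))
  }
  list(rec = rec, hyp = hyp, truth = truth)
}

# Same-family events on a shared channel closer than 0.5 s break the
# detectors' separability assumption; warn rather than fail.
warn_close_events <- function(plan) {
  fam <- function(k) ifelse(k %in% c("sw", "delta"), "sw_delta", "spindle")
  for (i in seq_len(max(nrow(plan) - 1, 0))) {
    for (j in (i + 1):nrow(plan)) {
      if (fam(plan$kind[i]) != fam(plan$kind[j])) next
      if (length(intersect(plan$channels[[i]], plan$channels[[j]])) == 0) next
      gap <- max(plan$onset_s[i], plan$onset_s[j]) -
        min(plan$onset_s[i] + plan$duration_s[i],
            plan$onset_s[j] + plan$duration_s[j])
      if (gap < 0.5) {
        warning("same-family events closer than 0.5 s on a shared channel; ",
                "detector separability is not guaranteed", call. = FALSE)
        return(invisible(NULL))
      }
    }
  }
  invisible(NULL)
}

#' Randomized plan of well-separated planted events
#'
#' Draws non-overlapping event onsets within the epochs of the requested
#' stages, with frequencies sampled away from the family class boundaries,
#' producing a plan suitable for detector validation (planted events are
#' separable by construction: minimum gap `min_gap_s` between events on the
#' same channel).
#'
#' @param config A [psg_sim_config()].
#' @param stage_blocks Stage per 30-s epoch (as in [generate_recording()]).
#' @param counts Named integer vector of event counts, e.g.
#'   `c(sw = 60, delta = 40, slow_spindle = 40, fast_spindle = 40)`.
#' @param stages Stages whose epochs may receive events (default N2, N3).
#' @param amplitudes_uV Named numeric: peak-to-peak amplitude per kind.
#'   Defaults scale with the background: slow waves 4x RMS (80 uV at the
#'   default floor), delta 6x (120 uV: a single-cycle delta wave loses up
#'   to a third of its amplitude to the 0.25-4 Hz detection band, and the
#'   planted amplitude keeps the filtered wave well inside the detector's
#'   50-300 uV acceptance window), spindles 3x (60 uV).
#' @param channels Channels the events are planted on; each event is
#'   assigned one channel cyclically.
#' @param min_gap_s Minimum gap between events on the same channel (s).
#' @param boundary_margin_hz Frequencies are drawn at least this far from
#'   the class boundaries (1.5, 12 Hz). Band-edge limits are fixed at
#'   physiologically typical values (slow waves 0.9-1.2 Hz, delta up to
#'   3.2 Hz, slow spindles from 9.5 Hz, fast spindles up to 15 Hz), clear
#'   of the detection-band transition edges.
#'
#' @return Tibble of planted events (rows as from [planted_event()]).
#' @export
plan_events <- function(config, stage_blocks, counts,
                        stages = c("N2", "N3"),
                        amplitudes_uV = c(sw = 4, delta = 6,
                                          slow_spindle = 3,
                                          fast_spindle = 3) * config$noise_rms_uV,
                        channels = config$channel_labels,
                        min_gap_s = 2,
                        boundary_margin_hz = 0.3) {
  freq_rng <- list(
    sw = c(0.9, 1.5 - boundary_margin_hz),
    delta = c(1.5 + boundary_margin_hz, 3.2),
    slow_spindle = c(9.5, 12 - boundary_margin_hz),
    fast_spindle = c(12 + boundary_margin_hz, 15)
  )
  kinds <- rep(names(counts), counts)
  n_ev <- length(kinds)
  if (n_ev == 0) return(tibble::tibble())
  ok_epochs <- which(stage_blocks %in% stages) - 1L
  if (length(ok_epochs) == 0) stop("no epochs in the requested stages",
                                   call. = FALSE)
  # longest event is a 0.6 Hz slow wave (1.67 s); reserve 2 s per slot
  slot_s <- 2 + min_gap_s
  slots_per_epoch <- floor(30 / slot_s)
  slot_onsets <- as.vector(outer(
    (seq_len(slots_per_epoch) - 1) * slot_s + 0.2,
    ok_epochs * 30, `+`
  ))
  if (n_ev > length(slot_onsets)) {
    stop("too many events for the available N2/N3 time", call. = FALSE)
  }
  kinds <- sample(kinds)                        # interleave kinds over time
  onsets <- sort(sample(slot_onsets, n_ev))
  rows <- vector("list", n_ev)
  for (i in seq_len(n_ev)) {
    k <- kinds[i]
    f <- stats::runif(1, freq_rng[[k]][1], freq_rng[[k]][2])
    rows[[i]] <- planted_event(
      kind = k,
      channels = channels[(i - 1L) %% length(channels) + 1L],
      onset_s = onsets[i],
      frequency_hz = f,
      amplitude_uV = amplitudes_uV[[k]],
      duration_s = if (k %in% c("sw", "delta")) NULL else 1
    )
  }
  dplyr::bind_rows(rows)
}
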