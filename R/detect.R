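#' Detection parameters for NREM event detectors
#'
#' Bundles the thresholds of the slow-wave/delta and spindle detectors.
#' Defaults: slow-wave band 0.25-4 Hz, z-threshold 3.5 SD, amplitude
#' 50-300 uV peak-to-peak, duration 0.2-3 s, 0.5 s minimum gap, 1.5 Hz
#' slow-wave/delta split; spindle band 9-16 Hz, envelope z-threshold 3.5
#' with at least 50% of the event above it, amplitude 25-250 uV,
#' duration 0.5-3 s, 12 Hz slow/fast split.
#'
#' @param sw_band,sp_band Band edges in Hz for the two detector families.
#' @param sw_zthresh,sp_zthresh Threshold in SD units of the (masked)
#'   filtered trace / envelope.
#' @param sw_amp,sp_amp Peak-to-peak amplitude acceptance range, uV.
#' @param sw_dur,sp_dur Duration acceptance range, s.
#' @param sw_gap Minimum gap between separate events, s (same-family
#'   candidates closer than this are merged before the gates).
#' @param sw_delta_split Intrinsic frequency (Hz) separating slow waves
#'   (below) from delta waves (at or above).
#' @param sp_frac_above Minimum fraction of in-event samples whose
#'   envelope z-score exceeds `sp_zthresh`.
#' @param sp_slow_fast_split,sp_upper Spindle class split and upper
#'   frequency bound (Hz); events outside (9, `sp_upper`\] are dropped as
#'   unclassifiable.
#' @param sp_edge_z Envelope z-level whose crossings bracket a
#'   supra-threshold run and define the event boundaries; a lower bracketing bound completes the threshold rule (default z = 1).
#' @param sp_smooth_s Moving-average window (s) applied to the spline
#'   envelope before z-scoring. The spline through squared-trace maxima
#'   is an upper envelope and jagged at the crest spacing; smoothing at
#'   roughly one crest period (default 0.1 s) stabilizes the boundary
#'   crossings without blurring the event-scale shape.
#'
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(sw_band = c(0.25, 4), sw_zthresh = 3.5,
                             sw_amp = c(50, 300), sw_dur = c(0.2, 3),
                             sw_gap = 0.5, sw_delta_split = 1.5,
                             sp_band = c(9, 16), sp_zthresh = 3.5,
                             sp_frac_above = 0.5, sp_amp = c(25, 250),
                             sp_dur = c(0.5, 3), sp_slow_fast_split = 12,
                             sp_upper = 16, sp_edge_z = 1.0,
                             sp_smooth_s = 0.1) {
  stopifnot(sw_band[1] < sw_band[2], sp_band[1] < sp_band[2],
            sw_amp[1] < sw_amp[2], sp_amp[1] < sp_amp[2],
            sw_dur[1] < sw_dur[2], sp_dur[1] < sp_dur[2],
            sw_zthresh > 0, sp_zthresh > 0, sw_gap >= 0,
            sp_frac_above > 0, sp_frac_above <= 1)
  structure(
    list(sw_band = sw_band, sw_zthresh = sw_zthresh, sw_amp = sw_amp,
         sw_dur = sw_dur, sw_gap = sw_gap, sw_delta_split = sw_delta_split,
         sp_band = sp_band, sp_zthresh = sp_zthresh,
         sp_frac_above = sp_frac_above, sp_amp = sp_amp, sp_dur = sp_dur,
         sp_slow_fast_split = sp_slow_fast_split, sp_upper = sp_upper,
         sp_edge_z = sp_edge_z, sp_smooth_s = sp_smooth_s),
    class = "detection_params"
  )
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

local_minima <- function(x) local_maxima(-x)

# stage of the 30-s epoch containing time t (0-based half-open epochs)
stage_at <- function(hyp, t) {
  i <- pmin(floor(t / 30), nrow(hyp) - 1L) + 1L
  as.character(hyp$stage[i])
}

#' Detect slow waves and delta waves
#'
#' Band-pass filters each channel to the slow-wave band (0.25-4 Hz),
#' z-scores the trace over the masked (selected-stage, artifact-free)
#' samples, and takes every negative excursion whose trough exceeds the
#' z-threshold as a candidate. Candidates closer than the minimum gap are
#' merged (deepest trough kept). A candidate is accepted if the
#' peak-to-peak amplitude of the filtered trace (trough to the adjacent
#' positive half-wave peak) lies in the amplitude range and the implied
#' duration (one intrinsic period) lies in the duration range. The
#' intrinsic frequency is one over twice the peak-trough half-period.
#' Waveform landmarks (trough and following up-state peak) are timed on
#' a doubled-bandwidth trace (0.25-8 Hz; the detection band broadens a
#' single fast cycle and would bias the half-period high), with each
#' extremum's time taken as the midpoint of its half-maximum region —
#' determined on the steep flanks, where noise displaces it far less
#' than it displaces the flat extremum itself. Events below the 1.5 Hz
#' split are slow waves, the rest delta waves.
#'
#' @param rec An [eeg_recording()] (typically 0.5-30 Hz preprocessed).
#' @param mask Sample mask from [stage_mask()].
#' @param params A [detection_params()].
#' @param hyp Optional hypnogram used to tag each event with its stage.
#' @param night Night label stored with every event (default `NA`).
#'
#' @return Tibble with one row per event: `channel`, `night`, `stage`,
#'   `trough_time_s`, `first_peak_time_s`, `amplitude_uV`, `duration_s`,
#'   `intrinsic_freq_hz`, `kind`.
#' @export
detect_sw_delta <- function(rec, mask, params = detection_params(),
                            hyp = NULL, night = NA) {
  stopifnot(inherits(rec, "eeg_recording"), length(mask) == nrow(rec$signal))
  if (rec$sampling_rate < 100) {
    stop("sampling rate must be at least 100 Hz", call. = FALSE)
  }
  if (!any(mask)) {
    warning("mask selects no samples; returning no events", call. = FALSE)
    return(empty_sw_table())
  }
  rate <- rec$sampling_rate
  filt <- bandpass_fir(rec, params$sw_band[1], params$sw_band[2])
  # timing trace: doubled upper edge keeps a single-cycle waveform's
  # shape through 4 Hz (the detection band broadens it and biases the
  # half-period high) while still excluding spindle-band noise
  timing <- bandpass_fir(rec, params$sw_band[1],
                         min(2 * params$sw_band[2], 0.45 * rate))
  out <- lapply(rec$channel_labels, function(ch) {
    x <- filt$signal[, ch]
    mu <- mean(x[mask]); sigma <- stats::sd(x[mask])
    if (sigma == 0) return(NULL)
    z <- (x - mu) / sigma
    cand <- local_minima(z)
    cand <- cand[z[cand] <= -params$sw_zthresh & mask[cand]]
    cand <- merge_troughs(cand, z, round(params$sw_gap * rate))
    xr <- timing$signal[, ch]
    rows <- lapply(cand, function(i_t) {
      sw_candidate_row(x, xr, i_t, rate, params)
    })
    rows <- dplyr::bind_rows(rows)
    if (nrow(rows) > 0) rows$channel <- ch
    rows
  })
  ev <- dplyr::bind_rows(out)
  if (nrow(ev) == 0) return(empty_sw_table())
  ev$night <- night
  ev$stage <- if (!is.null(hyp)) stage_at(hyp, ev$trough_time_s) else NA_character_
  ev <- ev[order(ev$channel, ev$trough_time_s), ]
  tibble::as_tibble(ev[, c("channel", "night", "stage", "trough_time_s",
                           "first_peak_time_s", "amplitude_uV", "duration_s",
                           "intrinsic_freq_hz", "kind")])
}

empty_sw_table <- function() {
  tibble::tibble(channel = character(), night = character(),
                 stage = character(), trough_time_s = numeric(),
                 first_peak_time_s = numeric(), amplitude_uV = numeric(),
                 duration_s = numeric(), intrinsic_freq_hz = numeric(),
                 kind = character())
}

# keep the deepest trough among any run of troughs closer than gap samples
merge_troughs <- function(cand, z, gap) {
  if (length(cand) < 2) return(cand)
  keep <- integer(0)
  group <- c(cand[1])
  flush <- function(g) g[which.min(z[g])]
  for (i in cand[-1]) {
    if (i - group[length(group)] < gap) {
      group <- c(group, i)
    } else {
      keep <- c(keep, flush(group))
      group <- i
    }
  }
  c(keep, flush(group))
}

sw_candidate_row <- function(x, xr, i_t, rate, params) {
  n <- length(x)
  # peak on the detection-band trace: the largest positive value within
  # 1.5 s after the trough (the up-state after the down-state; 1.5 s is
  # the longest admissible half-period); preceding window as fallback.
  # The amplitude gates apply to this band-filtered waveform.
  srch <- round(1.5 * rate)
  pk <- function(y, center, dir) {
    idx <- if (dir > 0) seq(center, min(n, center + srch)) else
      seq(max(1L, center - srch), center)
    j <- idx[which.max(y[idx])]
    list(i = j, v = y[j])
  }
  best <- pk(x, i_t, +1)
  if (best$v <= 0) best <- pk(x, i_t, -1)
  if (best$v <= 0) return(NULL)
  amp <- best$v - x[i_t]
  # waveform timing on the wideband trace: the narrow detection band
  # broadens a single fast cycle and would bias the half-period high, so
  # landmark positions are measured on the preprocessed signal. Extremum
  # times are midpoints of the half-maximum regions: the flanks are
  # steep there, so noise displaces the estimate far less than it
  # displaces the flat extrema themselves.
  w2 <- round(0.15 * rate)
  lo2 <- max(1L, i_t - w2); hi2 <- min(n, i_t + w2)
  i_tr <- lo2 - 1L + which.min(xr[lo2:hi2])
  if (xr[i_tr] >= 0) return(NULL)
  best_r <- pk(xr, i_tr, +1)
  if (best_r$v <= 0) best_r <- pk(xr, i_tr, -1)
  if (best_r$v <= 0) return(NULL)
  m_tr <- half_height_midpoint(xr, i_tr, 0.5 * xr[i_tr], below = TRUE)
  m_pk <- half_height_midpoint(xr, best_r$i, 0.5 * best_r$v, below = FALSE)
  half_period <- abs(m_pk - m_tr) / rate
  if (half_period <= 0) return(NULL)
  dur <- 2 * half_period
  f <- 1 / dur
  if (amp < params$sw_amp[1] || amp > params$sw_amp[2]) return(NULL)
  if (dur < params$sw_dur[1] || dur > params$sw_dur[2]) return(NULL)
  tibble::tibble(
    trough_time_s = (i_t - 1) / rate,
    first_peak_time_s = (best_r$i - 1) / rate,
    amplitude_uV = amp,
    duration_s = dur,
    intrinsic_freq_hz = f,
    kind = ifelse(f < params$sw_delta_split, "sw", "delta")
  )
}

# midpoint (fractional sample index) of the contiguous region around i0
# where x is beyond `level` (below it for troughs, above for peaks)
half_height_midpoint <- function(x, i0, level, below) {
  s <- if (below) -1 else 1
  y <- s * x; lv <- s * level
  n <- length(y)
  a <- i0
  while (a > 1L && y[a - 1L] >= lv) a <- a - 1L
  b <- i0
  while (b < n && y[b + 1L] >= lv) b <- b + 1L
  # linear sub-sample interpolation at both edges
  ea <- if (a > 1L) a - (y[a] - lv) / (y[a] - y[a - 1L]) else a
  eb <- if (b < n) b + (y[b] - lv) / (y[b] - y[b + 1L]) else b
  (ea + eb) / 2
}

#' Detect slow and fast sleep spindles
#'
#' Band-pass filters each channel to the spindle band (9-16 Hz), squares
#' the trace, fits a cubic-spline envelope through the local maxima of the
#' squared trace, and z-scores the envelope over the masked samples.
#' Candidate events are runs with envelope z at or above the threshold,
#' extended outward to the bracketing crossings of the lower edge level
#' (z = 1); candidates closer than the minimum gap are merged. A candidate
#' is accepted if at least the required fraction of its samples stays
#' above the threshold, its duration and the peak-to-peak amplitude of the
#' band-filtered trace are within range, and at least three local maxima
#' support an intrinsic-frequency estimate. Spindles with intrinsic
#' frequency in (9, 12\] Hz are classed slow, in (12, 16\] fast; others are
#' dropped as unclassifiable.
#'
#' @inheritParams detect_sw_delta
#' @return Tibble with one row per event: `channel`, `night`, `stage`,
#'   `onset_s`, `offset_s`, `duration_s`, `amplitude_uV`,
#'   `intrinsic_freq_hz`, `kind`.
#' @export
detect_spindles <- function(rec, mask, params = detection_params(),
                            hyp = NULL, night = NA) {
  stopifnot(inherits(rec, "eeg_recording"), length(mask) == nrow(rec$signal))
  rate <- rec$sampling_rate
  if (rate < 4 * params$sp_band[2]) {
    stop("sampling rate too low for spindle-band content", call. = FALSE)
  }
  if (!any(mask)) {
    warning("mask selects no samples; returning no events", call. = FALSE)
    return(empty_spindle_table())
  }
  filt <- bandpass_fir(rec, params$sp_band[1], params$sp_band[2])
  out <- lapply(rec$channel_labels, function(ch) {
    x <- filt$signal[, ch]
    r <- x^2
    mx <- local_maxima(r)
    if (length(mx) < 4) return(NULL)
    env <- stats::spline(mx, r[mx], xout = seq_along(r))$y
    sm <- round(params$sp_smooth_s * rate)
    if (sm > 1) {
      env <- stats::filter(env, rep(1 / sm, sm), sides = 2)
      env[is.na(env)] <- 0
    }
    mu <- mean(env[mask]); sigma <- stats::sd(env[mask])
    if (sigma == 0) return(NULL)
    z <- (env - mu) / sigma
    cands <- spindle_candidates(z, mask, params, rate)
    rows <- lapply(cands, function(cd) {
      spindle_candidate_row(x, z, cd[1], cd[2], rate, params)
    })
    rows <- dplyr::bind_rows(rows)
    if (nrow(rows) > 0) rows$channel <- ch
    rows
  })
  ev <- dplyr::bind_rows(out)
  if (nrow(ev) == 0) return(empty_spindle_table())
  ev$night <- night
  ev$stage <- if (!is.null(hyp)) {
    stage_at(hyp, (ev$onset_s + ev$offset_s) / 2)
  } else NA_character_
  ev <- ev[order(ev$channel, ev$onset_s), ]
  tibble::as_tibble(ev[, c("channel", "night", "stage", "onset_s",
                           "offset_s", "duration_s", "amplitude_uV",
                           "intrinsic_freq_hz", "kind")])
}

empty_spindle_table <- function() {
  tibble::tibble(channel = character(), night = character(),
                 stage = character(), onset_s = numeric(),
                 offset_s = numeric(), duration_s = numeric(),
                 amplitude_uV = numeric(), intrinsic_freq_hz = numeric(),
                 kind = character())
}

# candidate [start, end] sample index pairs: supra-threshold runs inside
# the mask, extended to the bracketing crossings of the edge level, then
# gap-merged
spindle_candidates <- function(z, mask, params, rate) {
  hot <- z >= params$sp_zthresh & mask
  if (!any(hot)) return(list())
  d <- diff(c(FALSE, hot, FALSE))
  starts <- which(d == 1); ends <- which(d == -1) - 1L
  low <- z < params$sp_edge_z
  n <- length(z)
  spans <- lapply(seq_along(starts), function(k) {
    s <- starts[k]
    before <- which(low[seq_len(s)])
    s2 <- if (length(before) > 0) before[length(before)] + 1L else 1L
    e <- ends[k]
    after <- which(low[e:n])
    e2 <- if (length(after) > 0) e + after[1] - 2L else n
    c(s2, e2)
  })
  # merge spans separated by less than the minimum gap
  merged <- list()
  cur <- spans[[1]]
  gap <- round(params$sw_gap * rate)
  for (sp in spans[-1]) {
    if (sp[1] - cur[2] < gap) {
      cur[2] <- max(cur[2], sp[2])
    } else {
      merged <- c(merged, list(cur))
      cur <- sp
    }
  }
  c(merged, list(cur))
}

spindle_candidate_row <- function(x, z, s, e, rate, params) {
  dur <- (e - s + 1) / rate
  if (dur < params$sp_dur[1] || dur > params$sp_dur[2]) return(NULL)
  frac <- mean(z[s:e] >= params$sp_zthresh)
  if (frac < params$sp_frac_above) return(NULL)
  seg <- x[s:e]
  amp <- max(seg) - min(seg)
  if (amp < params$sp_amp[1] || amp > params$sp_amp[2]) return(NULL)
  # intrinsic frequency from the supra-threshold core, where the
  # oscillation dominates the band-filtered noise
  hot <- which(z[s:e] >= params$sp_zthresh)
  core <- if (length(hot) > 2) seg[hot[1]:hot[length(hot)]] else seg
  f <- spindle_intrinsic_frequency(core, rate)
  if (is.na(f)) return(NULL)
  if (f <= 9 || f > params$sp_upper) return(NULL)
  tibble::tibble(
    onset_s = (s - 1) / rate,
    offset_s = (e - 1) / rate,
    duration_s = dur,
    amplitude_uV = amp,
    intrinsic_freq_hz = f,
    kind = ifelse(f <= params$sp_slow_fast_split, "slow_spindle",
                  "fast_spindle")
  )
}

#' Intrinsic frequency of an oscillatory event waveform
#'
#' Time-domain estimate: the inverse of the mean period between successive
#' local maxima of the (band-filtered) event waveform, `f = 1 / <p>`.
#'
#' @param waveform Numeric vector, the band-filtered trace of one event.
#' @param rate Sampling rate in Hz.
#' @return Frequency in Hz, or `NA` if fewer than three local maxima
#'   support the estimate.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1 / 500)
#' spindle_intrinsic_frequency(sin(2 * pi * 13 * t), 500)
spindle_intrinsic_frequency <- function(waveform, rate, crest_floor = 0.2) {
  mx <- local_maxima(waveform)
  mx <- mx[waveform[mx] > 0]            # oscillation crests only
  if (length(mx) >= 3) {
    # keep genuine crests: edge maxima at noise level would stretch the
    # mean period and bias the estimate low
    mx <- mx[waveform[mx] >= crest_floor * max(waveform[mx])]
  }
  if (length(mx) < 3) return(NA_real_)
  p <- diff(mx)
  # a crest lost to noise merges two periods into one; such doubled
  # intervals would bias the mean, so they are excluded before averaging
  p <- p[p <= 1.5 * stats::median(p)]
  if (length(p) < 2) return(NA_real_)
  rate / mean(p)
}

#' Per-condition event summaries
#'
#' Aggregates an event table into densities and mean properties per
#' (channel, stage, night, kind) cell — and per subject when a `subject`
#' column is present. Density is events per masked minute of the matching
#' (stage, night) cell.
#'
#' @param events Event tibble from [detect_sw_delta()] /
#'   [detect_spindles()] (rows may be bound together; the amplitude,
#'   duration and intrinsic-frequency columns are shared).
#' @param masked_minutes Either a single number of masked minutes applied
#'   to every cell, or a tibble with columns `stage`, `night`, `minutes`.
#' @return Tibble with `n_events`, `density_per_min`, `mean_amplitude_uV`,
#'   `mean_duration_s`, `mean_freq_hz` per grouping cell.
#' @export
summarize_events <- function(events, masked_minutes) {
  keys <- intersect(c("subject", "channel", "stage", "night", "kind"),
                    names(events))
  if (nrow(events) == 0) {
    return(tibble::tibble(n_events = integer(), density_per_min = numeric(),
                          mean_amplitude_uV = numeric(),
                          mean_duration_s = numeric(),
                          mean_freq_hz = numeric()))
  }
  stats_tbl <- events |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_events = dplyr::n(),
      mean_amplitude_uV = mean(.data$amplitude_uV),
      mean_duration_s = mean(.data$duration_s),
      mean_freq_hz = mean(.data$intrinsic_freq_hz),
      .groups = "drop"
    )
  if (is.data.frame(masked_minutes)) {
    stats_tbl <- dplyr::left_join(
      stats_tbl, masked_minutes,
      by = intersect(c("stage", "night"), names(masked_minutes))
    )
  } else {
    stats_tbl$minutes <- masked_minutes
  }
  if (any(is.na(stats_tbl$minutes) | stats_tbl$minutes <= 0)) {
    warning("cells with zero/unknown masked minutes: density set to NA",
            call. = FALSE)
  }
  stats_tbl$density_per_min <- ifelse(
    !is.na(stats_tbl$minutes) & stats_tbl$minutes > 0,
    stats_tbl$n_events / stats_tbl$minutes, NA_real_
  )
  dplyr::select(stats_tbl, dplyr::all_of(keys), "n_events",
                "density_per_min", "mean_amplitude_uV", "mean_duration_s",
                "mean_freq_hz")
}
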