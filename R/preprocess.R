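#' Zero-phase Hamming-window FIR band-pass filter
#'
#' Applies a linear-phase FIR band-pass (Hamming window design, via
#' [signal::fir1()]) with exact group-delay compensation, so the output is
#' zero-phase. Filtering is done by FFT overlap-free convolution on a
#' zero-padded copy of each channel, which keeps long low-cutoff kernels
#' cheap. The default preprocessing band is 0.5-30 Hz.
#'
#' The kernel order follows `3.3 * rate / transition_width` rounded up to
#' odd, with `transition_width = clamp(lo, 0.25, 2)` Hz by default: the
#' transition band tracks the low cutoff for slow bands but is capped at
#' 2 Hz so that spindle-band filters stay selective. Hamming windows give
#' > 50 dB stopband attenuation.
#'
#' @param rec An [eeg_recording()].
#' @param lo,hi Band edges in Hz, `0 < lo < hi < rate/2`.
#' @param transition_width_hz Transition bandwidth in Hz (see above).
#' @return A filtered [eeg_recording()].
#' @export
#' @examples
#' rec <- eeg_recording(matrix(sin(2 * pi * 10 * (1:2000) / 200), ncol = 1,
#'                             dimnames = list(NULL, "Cz")), 200)
#' out <- bandpass_fir(rec, 0.5, 30)
bandpass_fir <- function(rec, lo = 0.5, hi = 30,
                         transition_width_hz = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  rate <- rec$sampling_rate
  if (!(lo > 0 && lo < hi && hi < rate / 2)) {
    stop("band edges must satisfy 0 < lo < hi < rate/2", call. = FALSE)
  }
  if (is.null(transition_width_hz)) {
    transition_width_hz <- min(max(lo, 0.25), 2)
  }
  order <- ceiling(3.3 * rate / transition_width_hz)
  if (order %% 2 == 1) order <- order + 1  # even order -> odd-length kernel
  b <- signal::fir1(order, c(lo, hi) / (rate / 2), type = "pass",
                    window = signal::hamming(order + 1))
  rec$signal <- apply(rec$signal, 2, fft_filt_zerophase, b = b)
  rec
}

# Convolve with a symmetric (linear-phase) kernel by FFT and remove the
# group delay of (length(b)-1)/2 samples; zero padding at both ends.
fft_filt_zerophase <- function(x, b) {
  n <- length(x)
  m <- length(b)
  delay <- (m - 1L) %/% 2L
  nfft <- stats::nextn(n + m - 1L, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  B <- stats::fft(c(b, numeric(nfft - m)))
  y <- Re(stats::fft(X * B, inverse = TRUE)) / nfft
  y[(delay + 1L):(delay + n)]
}

#' Re-reference to linked mastoids
#'
#' Subtracts the mean of the two mastoid channels from every other channel
#' and drops the mastoids from the output, reproducing the standard
#' linked-mastoid reference montage. Synthetic recordings typically omit
#' mastoids; in that case skip this step.
#'
#' @param rec An [eeg_recording()].
#' @param m1,m2 Mastoid channel labels (e.g. `"M1"`, `"M2"`).
#' @return A re-referenced [eeg_recording()] without the mastoid channels.
#' @export
rereference_linked_mastoids <- function(rec, m1 = "M1", m2 = "M2") {
  stopifnot(inherits(rec, "eeg_recording"))
  miss <- setdiff(c(m1, m2), rec$channel_labels)
  if (length(miss) > 0) {
    stop("mastoid channel(s) ", paste(miss, collapse = ", "),
         " not present; skip re-referencing for recordings without mastoids",
         call. = FALSE)
  }
  ref <- (rec$signal[, m1] + rec$signal[, m2]) / 2
  keep <- setdiff(rec$channel_labels, c(m1, m2))
  sig <- rec$signal[, keep, drop = FALSE] - ref
  eeg_recording(sig, rec$sampling_rate, keep,
                reference = sprintf("linked mastoids (%s, %s)", m1, m2))
}
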