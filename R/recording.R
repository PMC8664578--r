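#' Multi-channel EEG recording
#'
#' Constructs an `eeg_recording`, the package's container for a
#' multi-channel scalp EEG signal. The signal is stored as a numeric
#' matrix with one column per channel (samples in rows) in microvolts.
#'
#' @param signal Numeric matrix, samples x channels, in uV. Column names,
#'   if present, are used as channel labels.
#' @param sampling_rate Sampling rate in Hz (scalar, > 0).
#' @param channel_labels Character vector of channel labels (10-20 names
#'   for scalp EEG). Defaults to the column names of `signal`.
#' @param reference Free-text description of the reference montage.
#'
#' @return An object of class `eeg_recording`: a list with elements
#'   `signal`, `sampling_rate`, `channel_labels`, `reference`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(1000), ncol = 2,
#'                             dimnames = list(NULL, c("Fz", "Cz"))), 100)
#' rec
eeg_recording <- function(signal, sampling_rate,
                          channel_labels = colnames(signal),
                          reference = "unknown") {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(ncol(signal)))
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != ncol(signal)) {
    stop("`channel_labels` must name every signal column", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  colnames(signal) <- channel_labels
  structure(
    list(signal = signal,
         sampling_rate = as.numeric(sampling_rate),
         channel_labels = channel_labels,
         reference = reference),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  dur <- nrow(x$signal) / x$sampling_rate
  cat(sprintf("<eeg_recording> %d channels x %d samples (%.1f s @ %g Hz)\n",
              ncol(x$signal), nrow(x$signal), dur, x$sampling_rate))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  cat("  reference:", x$reference, "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$signal)

#' Recording duration in seconds
#' @param rec An `eeg_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  nrow(rec$signal) / rec$sampling_rate
}

#' Construct a hypnogram
#'
#' A hypnogram is a tibble with one row per 30-s scoring epoch, holding the
#' AASM stage and an artifact flag. Epochs are 0-based and half-open:
#' epoch `i` covers `[30 i, 30 (i + 1))` seconds.
#'
#' @param stages Character/factor vector of stages, one per 30-s epoch;
#'   levels `W`, `N1`, `N2`, `N3`, `REM`.
#' @param artifact Logical vector flagging epochs removed for high-amplitude
#'   noise or artifacts; recycled if length 1.
#' @param epoch_len_s Epoch length in seconds; fixed at 30 for AASM scoring.
#'
#' @return A tibble with columns `epoch` (0-based integer), `stage`
#'   (factor) and `artifact` (logical).
#' @export
#' @examples
#' hypnogram(c("W", "N1", "N2", "N2", "N3"))
hypnogram <- function(stages, artifact = FALSE, epoch_len_s = 30) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), sleep_stage_levels())
  if (length(bad) > 0) {
    stop("unknown sleep stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (epoch_len_s != 30) {
    stop("hypnogram epochs are 30 s by convention", call. = FALSE)
  }
  artifact <- rep_len(as.logical(artifact), length(stages))
  tibble::tibble(
    epoch = seq_along(stages) - 1L,
    stage = factor(stages, levels = sleep_stage_levels()),
    artifact = artifact
  )
}

#' AASM stage levels used throughout the package
#' @return Character vector `c("W", "N1", "N2", "N3", "REM")`.
#' @export
sleep_stage_levels <- function() c("W", "N1", "N2", "N3", "REM")

#' Sample-level mask for selected sleep stages
#'
#' Expands a hypnogram into a per-sample logical mask selecting the samples
#' that fall in the requested stages and outside artifact-flagged epochs.
#' This realizes the "noise-free whole epochs" selection used for all event
#' detection and whole-epoch spectral analyses.
#'
#' @param hyp A hypnogram tibble (see [hypnogram()]).
#' @param stages Character vector of stages to include, e.g.
#'   `c("N2", "N3")`.
#' @param rec The `eeg_recording` the mask must cover.
#'
#' @return Logical vector with one element per signal sample.
#' @export
#' @examples
#' hyp <- hypnogram(c("W", "N2", "N2", "N3"))
#' rec <- eeg_recording(matrix(0, 4 * 30 * 100, 1), 100)
#' sum(stage_mask(hyp, c("N2", "N3"), rec)) / 100  # 90 s selected
stage_mask <- function(hyp, stages, rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  bad <- setdiff(stages, sleep_stage_levels())
  if (length(bad) > 0) {
    stop("unknown sleep stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(rec$signal)
  spe <- round(30 * rec$sampling_rate)  # samples per 30-s epoch
  if (nrow(hyp) * spe < n - spe) {
    stop("hypnogram does not cover the recording", call. = FALSE)
  }
  keep_epoch <- hyp$stage %in% stages & !hyp$artifact
  mask <- rep(keep_epoch, each = spe)
  length(mask) <- n          # clip or NA-pad to the signal length
  mask[is.na(mask)] <- FALSE
  mask
}

#' Read / write hypnograms as CSV
#'
#' Plain-text exchange format: one row per 30-s epoch with columns
#' `epoch` (0-based index), `stage` (W/N1/N2/N3/REM) and `artifact`
#' (0/1 or logical).
#'
#' @param path CSV file path.
#' @return `read_hypnogram()` returns a hypnogram tibble (see
#'   [hypnogram()]); `write_hypnogram()` returns `path` invisibly.
#' @export
read_hypnogram <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("epoch", "stage")
  if (!all(need %in% names(df))) {
    stop("hypnogram CSV needs columns `epoch` and `stage`", call. = FALSE)
  }
  df <- df[order(df$epoch), ]
  if (!identical(as.integer(df$epoch), seq_len(nrow(df)) - 1L)) {
    stop("`epoch` must be the complete 0-based sequence", call. = FALSE)
  }
  art <- if ("artifact" %in% names(df)) as.logical(df$artifact) else FALSE
  hypnogram(df$stage, artifact = art)
}

#' @rdname read_hypnogram
#' @param hyp A hypnogram tibble.
#' @export
write_hypnogram <- function(hyp, path) {
  out <- data.frame(epoch = hyp$epoch, stage = as.character(hyp$stage),
                    artifact = as.integer(hyp$artifact))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
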