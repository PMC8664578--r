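#' Write a recording to an EDF file
#'
#' Writes a plain European Data Format (EDF) file: 16-bit little-endian
#' samples with per-channel physical scaling, 1-s data records. If the
#' recording length is not a whole number of seconds the final record is
#' zero-padded (the pad is returned by the reader; keep durations integral
#' for exact round trips).
#'
#' @param rec An [eeg_recording()] with signal in uV.
#' @param path Output file path.
#' @param patient,recording_id Free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, patient = "X", recording_id = "nremtools") {
  stopifnot(inherits(rec, "eeg_recording"))
  rate <- rec$sampling_rate
  if (abs(rate - round(rate)) > 1e-9) {
    stop("EDF export requires an integer sampling rate", call. = FALSE)
  }
  rate <- as.integer(round(rate))
  ns <- ncol(rec$signal)
  n <- nrow(rec$signal)
  n_rec <- ceiling(n / rate)
  pad <- n_rec * rate - n
  sig <- rec$signal
  if (pad > 0) sig <- rbind(sig, matrix(0, pad, ns))

  # physical range symmetric about zero, covering the data
  pmax <- pmax(apply(abs(sig), 2, max), 1)
  pmin <- -pmax
  dmin <- -32768; dmax <- 32767

  fixed <- function(x, w) {
    x <- substr(format(x, width = w), 1, w)
    formatC(x, width = w, flag = "-")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    fixed("0", 8), fixed(patient, 80), fixed(recording_id, 80),
    fixed(format(Sys.Date(), "%d.%m.%y"), 8), fixed("00.00.00", 8),
    fixed(as.character(256 * (ns + 1)), 8), fixed("", 44),
    fixed(as.character(n_rec), 8), fixed("1", 8),
    fixed(as.character(ns), 4)
  )
  writeChar(hdr, con, eos = NULL)
  sig_field <- function(vals, w) {
    writeChar(paste(vapply(vals, fixed, "", w = w), collapse = ""),
              con, eos = NULL)
  }
  sig_field(rec$channel_labels, 16)
  sig_field(rep("", ns), 80)                       # transducer
  sig_field(rep("uV", ns), 8)                      # physical dimension
  sig_field(sprintf("%.6g", pmin), 8)
  sig_field(sprintf("%.6g", pmax), 8)
  sig_field(rep(as.character(dmin), ns), 8)
  sig_field(rep(as.character(dmax), ns), 8)
  sig_field(rep("", ns), 80)                       # prefiltering
  sig_field(rep(as.character(rate), ns), 8)        # samples per record
  sig_field(rep("", ns), 32)

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * rate + 1L):(r * rate)
    for (ch in seq_len(ns)) {
      dig <- round((sig[idx, ch] - pmin[ch]) * scale[ch] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Parses a plain EDF (or the EDF-compatible subset of EDF+) file in which
#' all signals share one sampling rate, and returns the physically scaled
#' signal in the units declared in the header (uV for files written by
#' [write_edf()]).
#'
#' @param path Path to an EDF file.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8); rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || is.na(rec_dur)) {
    stop("not a parseable EDF header", call. = FALSE)
  }
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16); rdv(80)
  units <- rdv(8)
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))                        # samples per record
  rdv(32)
  if (any(is.na(c(pmin, pmax, dmin, dmax, spr)))) {
    stop("malformed EDF signal headers", call. = FALSE)
  }
  if (length(unique(spr)) != 1L) {
    stop("signals with mixed sampling rates are not supported", call. = FALSE)
  }
  rate <- spr[1] / rec_dur
  expected <- n_rec * sum(spr) * 2
  payload <- readBin(con, "integer", n = n_rec * sum(spr), size = 2L,
                     signed = TRUE, endian = "little")
  if (length(payload) < n_rec * sum(spr)) {
    stop("EDF payload truncated: expected ", expected, " bytes",
         call. = FALSE)
  }
  sig <- matrix(0, n_rec * spr[1], ns)
  scale <- (pmax - pmin) / (dmax - dmin)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- payload[(pos + 1L):(pos + spr[ch])]
      pos <- pos + spr[ch]
      rows <- ((r - 1L) * spr[ch] + 1L):(r * spr[ch])
      sig[rows, ch] <- (dig - dmin[ch]) * scale[ch] + pmin[ch]
    }
  }
  colnames(sig) <- make.unique(labels)
  eeg_recording(sig, rate, reference = "as recorded")
}
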