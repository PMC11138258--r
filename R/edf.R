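#' EEG recordings and European Data Format (EDF) I/O
#'
#' A recording is the in-memory container for one subject-session of
#' multichannel EEG: a channels-by-samples matrix in microvolts plus sampling
#' rate and session metadata. Recordings round-trip through standard 16-bit
#' EDF files: `write_edf()` scales each channel into the signed 16-bit
#' digital range, so a read-back differs from the original by at most one
#' quantization step (physical range / 2^15) per sample.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz (positive integer).
#' @param channel_labels Character vector, one label per row of `data`.
#' @param subject_id,session_id Identifiers stored in the EDF header.
#' @param session_datetime A `POSIXct` recording start time.
#' @return `eeg_recording()` and `read_edf()` return an `eeg_recording`
#'   object; `write_edf()` invisibly returns `path`.
#' @export
eeg_recording <- function(data, fs, channel_labels = rownames(data),
                          subject_id = "S1", session_id = "V1",
                          session_datetime = as.POSIXct("2024-01-01 09:00:00", tz = "UTC")) {
  data <- as.matrix(data)
  if (is.null(channel_labels)) channel_labels <- paste0("E", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data)) {
    stop_validation("`channel_labels` must have one entry per channel (row of `data`).")
  }
  if (any(!is.finite(data))) stop_validation("Recording data must be finite.")
  assert_scalar_number(fs, "fs", lower = .Machine$double.eps)
  rownames(data) <- channel_labels
  structure(
    list(
      data = data, fs = fs, channel_labels = as.character(channel_labels),
      subject_id = as.character(subject_id), session_id = as.character(session_id),
      session_datetime = as.POSIXct(session_datetime, tz = "UTC")
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> subject %s session %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$session_id, nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs
  ))
  invisible(x)
}

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' @rdname eeg_recording
#' @param rec An `eeg_recording`.
#' @param path File path.
#' @export
write_edf <- function(rec, path) {
  if (!inherits(rec, "eeg_recording")) stop_validation("`rec` must be an eeg_recording.")
  data <- rec$data
  if (any(!is.finite(data))) stop_validation("Cannot write non-finite samples to EDF.")
  fs <- rec$fs
  if (fs != round(fs)) stop_validation("EDF writer requires an integer sampling rate.")
  ns <- nrow(data)
  n_samp <- ncol(data)
  n_rec <- n_samp %/% fs
  if (n_rec < 1 || n_rec * fs != n_samp) {
    stop_validation("EDF writer requires a whole number of 1 s data records.")
  }

  # Per-channel symmetric physical range; digital range -32767..32767 keeps
  # the zero level exactly representable.
  pmax_ <- pmax(apply(abs(data), 1, max), 1)
  pmax_ <- ceiling(pmax_ * 1000) / 1000
  scale <- pmax_ / 32767

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wr <- function(s) writeBin(charToRaw(s), con)

  dt <- rec$session_datetime
  wr(edf_pad("0", 8))
  wr(edf_pad(rec$subject_id, 80))
  wr(edf_pad(rec$session_id, 80))
  wr(edf_pad(format(dt, "%d.%m.%y", tz = "UTC"), 8))
  wr(edf_pad(format(dt, "%H.%M.%S", tz = "UTC"), 8))
  wr(edf_pad(256 * (ns + 1), 8))
  wr(edf_pad("", 44))
  wr(edf_pad(n_rec, 8))
  wr(edf_pad("1", 8)) # record duration, seconds
  wr(edf_pad(ns, 4))

  for (lab in rec$channel_labels) wr(edf_pad(lab, 16))
  for (i in seq_len(ns)) wr(edf_pad("EEG", 80))
  for (i in seq_len(ns)) wr(edf_pad("uV", 8))
  for (i in seq_len(ns)) wr(edf_num(-pmax_[i], 8))
  for (i in seq_len(ns)) wr(edf_num(pmax_[i], 8))
  for (i in seq_len(ns)) wr(edf_pad("-32767", 8))
  for (i in seq_len(ns)) wr(edf_pad("32767", 8))
  for (i in seq_len(ns)) wr(edf_pad("", 80))
  for (i in seq_len(ns)) wr(edf_pad(fs, 8))
  for (i in seq_len(ns)) wr(edf_pad("", 32))

  dig <- round(data / scale)
  dig[dig > 32767] <- 32767
  dig[dig < -32767] <- -32767
  storage.mode(dig) <- "integer"
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    # signals are stored sequentially within each record
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf_header_field <- function(con, width) {
  trimws(rawToChar(readBin(con, "raw", n = width)))
}

#' @rdname eeg_recording
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop_format(paste0("EDF file not found: ", path))
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  fld <- function(w) read_edf_header_field(con, w)

  version <- fld(8)
  if (version != "0") stop_format(paste0("Not an EDF file (version field '", version, "'): ", path))
  subject_id <- fld(80)
  session_id <- fld(80)
  startdate <- fld(8)
  starttime <- fld(8)
  header_bytes <- suppressWarnings(as.integer(fld(8)))
  fld(44)
  n_rec <- suppressWarnings(as.integer(fld(8)))
  rec_dur <- suppressWarnings(as.numeric(fld(8)))
  ns <- suppressWarnings(as.integer(fld(4)))
  if (anyNA(c(header_bytes, n_rec, rec_dur, ns)) || ns < 1 || n_rec < 1) {
    stop_format(paste0("Malformed EDF header: ", path))
  }

  labels <- vapply(seq_len(ns), function(i) fld(16), "")
  for (i in seq_len(ns)) fld(80) # transducer
  for (i in seq_len(ns)) fld(8) # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(fld(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(fld(8)), 0)
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(fld(8)), 0)
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(fld(8)), 0)
  for (i in seq_len(ns)) fld(80) # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(fld(8)), 0L)
  for (i in seq_len(ns)) fld(32)

  if (length(unique(spr)) != 1L) {
    stop_validation("EDF files with mixed per-signal sampling rates are not supported.")
  }
  fs <- spr[1] / rec_dur
  n_samp <- n_rec * spr[1]
  data <- matrix(0, nrow = ns, ncol = n_samp)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = ns * spr[1], size = 2, endian = "little", signed = TRUE)
    if (length(block) < ns * spr[1]) stop_format(paste0("Truncated EDF data section: ", path))
    data[, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
      t(matrix(block, nrow = spr[1], ncol = ns))
  }
  # digital -> physical
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  data <- data * gain + (pmin_ - dmin_ * gain)
  if (any(!is.finite(data))) stop_format(paste0("Non-finite samples decoded from: ", path))

  dt <- as.POSIXct(paste(startdate, starttime), format = "%d.%m.%y %H.%M.%S", tz = "UTC")
  if (is.na(dt)) dt <- as.POSIXct("2000-01-01 00:00:00", tz = "UTC")
  eeg_recording(data, fs,
    channel_labels = labels,
    subject_id = subject_id, session_id = session_id, session_datetime = dt
  )
}
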