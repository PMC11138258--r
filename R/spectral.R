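#' Frequency-band scheme for relative band power
#'
#' The five canonical bands on the 0.5 Hz Welch grid: delta 2-3.5, theta
#' 4-7.5, alpha 8-12.5, beta 13-30 and gamma 30-80 Hz, with the mains
#' stopband 55-65 Hz excluded from the gamma average (but retained in the
#' 2-80 Hz normalizing total). A bin belongs to a band if `lo <= f <= hi`;
#' the shared 30 Hz edge is assigned to the lower band (beta).
#'
#' @return A `band_scheme` list.
#' @export
band_scheme <- function() {
  structure(
    list(
      bands = band_edges(),
      gamma_stopband = c(55, 65),
      total_range = c(2, 80)
    ),
    class = "band_scheme"
  )
}

#' Welch power spectral density of kept epochs
#'
#' Averages Hanning-windowed periodograms of `window_s`-second segments at
#' 50% overlap, independently per channel, with window power normalization
#' (so the PSD integrates to signal variance). Segments are drawn from the
#' concatenation of kept epochs within each contiguous run — no segment
#' spans a rejection gap. With 2 s windows the frequency resolution is
#' 0.5 Hz.
#'
#' @param es An `eeg_epochs` object with at least one kept epoch.
#' @param window_s Welch window length in seconds (default 2).
#' @param overlap Fractional overlap between consecutive segments.
#' @return A `power_spectrum` list with `freqs` (Hz), `absolute`
#'   (channels x freqs, uV^2/Hz), `n_segments` and channel labels.
#' @export
welch_psd <- function(es, window_s = 2, overlap = 0.5) {
  stopifnot(inherits(es, "eeg_epochs"))
  if (!any(es$kept_mask)) stop_data_quality("No kept epochs to estimate a spectrum from.")
  fs <- es$fs
  nw <- round(window_s * fs)
  hop <- max(1L, round(nw * (1 - overlap)))
  n_ch <- dim(es$epochs)[2]
  spe <- dim(es$epochs)[3]

  win <- hann_window(nw)
  u <- sum(win^2)
  nfreq <- nw %/% 2 + 1
  acc <- matrix(0, n_ch, nfreq)
  n_seg <- 0L

  kept <- which(es$kept_mask)
  runs <- split(kept, cumsum(c(1, diff(kept) != 1)))
  for (run in runs) {
    n_samp <- length(run) * spe
    if (n_samp < nw) next
    # channels x samples concatenation of this contiguous run
    xcat <- matrix(aperm(es$epochs[run, , , drop = FALSE], c(2, 3, 1)), nrow = n_ch)
    starts <- seq(1, n_samp - nw + 1, by = hop)
    for (s0 in starts) {
      seg <- xcat[, s0:(s0 + nw - 1), drop = FALSE]
      seg <- sweep(seg, 2, win, "*")
      sp <- mvfft(t(seg))
      p <- (Mod(sp[seq_len(nfreq), , drop = FALSE])^2) / (fs * u)
      p[2:(nfreq - 1), ] <- 2 * p[2:(nfreq - 1), ] # one-sided
      acc <- acc + t(p)
      n_seg <- n_seg + 1L
    }
  }
  if (n_seg == 0L) stop_data_quality("Kept data shorter than one Welch window.")

  structure(
    list(
      freqs = (seq_len(nfreq) - 1) * fs / nw,
      absolute = acc / n_seg,
      relative = NULL, rel_freqs = NULL, undefined = rep(FALSE, n_ch),
      fs = fs, n_segments = n_seg, channel_labels = es$channel_labels
    ),
    class = "power_spectrum"
  )
}

hann_window <- function(n) {
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

#' Relative power over the 2-80 Hz grid
#'
#' Divides each channel's absolute power bins in \[2, 80\] Hz by that
#' channel's summed power over the same bins; bins outside the range are
#' excluded from both numerator and denominator, so each channel's relative
#' values sum to exactly 1. A channel with zero total power is flagged
#' undefined (and later dropped from montage averaging) with a warning.
#'
#' @param ps A `power_spectrum` from [welch_psd()].
#' @param total_range Normalization range in Hz.
#' @return The `power_spectrum` with `relative` (channels x banded bins) and
#'   `rel_freqs` filled.
#' @export
relative_power <- function(ps, total_range = c(2, 80)) {
  stopifnot(inherits(ps, "power_spectrum"))
  sel <- ps$freqs >= total_range[1] & ps$freqs <= total_range[2]
  if (!any(sel)) stop_validation("No frequency bins inside the normalization range.")
  abs_sel <- ps$absolute[, sel, drop = FALSE]
  tot <- rowSums(abs_sel)
  undef <- tot <= 0
  if (any(undef)) {
    warn(sprintf(
      "%d channel(s) with zero total power flagged undefined: %s",
      sum(undef), paste(ps$channel_labels[undef], collapse = ", ")
    ))
    tot[undef] <- 1
  }
  ps$relative <- abs_sel / tot
  ps$relative[undef, ] <- NA_real_
  ps$rel_freqs <- ps$freqs[sel]
  ps$undefined <- undef
  ps
}

band_bin_assignment <- function(rel_freqs, scheme = band_scheme()) {
  assign <- rep(NA_character_, length(rel_freqs))
  for (b in names(scheme$bands)) {
    e <- scheme$bands[[b]]
    hit <- is.na(assign) & rel_freqs >= e[1] & rel_freqs <= e[2]
    assign[hit] <- b
  }
  # mains stopband bins are excluded from the gamma average only
  sb <- scheme$gamma_stopband
  assign[assign == "gamma" & rel_freqs >= sb[1] & rel_freqs <= sb[2]] <- NA_character_
  assign
}

#' Per-channel relative band power
#'
#' Arithmetic mean of the relative-power bins assigned to each band (gamma
#' excluding the 55-65 Hz stopband bins).
#'
#' @param ps A `power_spectrum` with the relative part computed.
#' @param scheme A [band_scheme()].
#' @return A bands x channels numeric matrix.
#' @export
band_powers <- function(ps, scheme = band_scheme()) {
  stopifnot(inherits(ps, "power_spectrum"))
  if (is.null(ps$relative)) stop_validation("Call relative_power() first.")
  assign <- band_bin_assignment(ps$rel_freqs, scheme)
  out <- vapply(names(scheme$bands), function(b) {
    idx <- which(assign == b)
    if (!length(idx)) {
      return(rep(NA_real_, nrow(ps$relative)))
    }
    rowMeans(ps$relative[, idx, drop = FALSE])
  }, numeric(nrow(ps$relative)))
  out <- matrix(out,
    nrow = nrow(ps$relative), ncol = length(scheme$bands),
    dimnames = list(ps$channel_labels, names(scheme$bands))
  )
  t(out)
}

#' Individual peak frequency per channel
#'
#' The frequency of the maximum of the log10-scaled relative power within
#' the 5-14 Hz window; exact ties resolve to the lower frequency. Monotone
#' (peakless) spectra therefore return the 5 Hz window edge; the count of
#' such edge results is attached as the `"n_edge"` attribute.
#'
#' @param ps A `power_spectrum` with the relative part computed.
#' @param window Search window in Hz.
#' @return Named numeric vector of per-channel peak frequencies (Hz).
#' @export
individual_peak_frequency <- function(ps, window = c(5, 14)) {
  stopifnot(inherits(ps, "power_spectrum"))
  if (is.null(ps$relative)) stop_validation("Call relative_power() first.")
  idx <- which(ps$rel_freqs >= window[1] & ps$rel_freqs <= window[2])
  if (!length(idx)) stop_validation("IPF window contains no frequency bins.")
  f_win <- ps$rel_freqs[idx]
  ipf <- apply(ps$relative[, idx, drop = FALSE], 1, function(r) {
    if (all(is.na(r))) {
      return(NA_real_)
    }
    lr <- log10(r)
    f_win[which.max(lr)] # which.max takes the first (lowest-frequency) tie
  })
  n_edge <- sum(ipf %in% range(f_win), na.rm = TRUE)
  structure(setNames(ipf, ps$channel_labels), n_edge = n_edge)
}

#' Average per-channel features over the analysis montage
#'
#' Unweighted mean over non-excluded, defined channels.
#'
#' @param values Named per-channel numeric vector.
#' @param montage An `eeg_montage`.
#' @return Scalar montage average.
#' @export
montage_average <- function(values, montage) {
  keep <- intersect(names(values), analysis_channels(montage))
  v <- values[keep]
  n_bad <- sum(is.na(v))
  if (n_bad > 0) {
    warn(sprintf("Dropping %d undefined channel(s) from the montage average.", n_bad))
    v <- v[!is.na(v)]
  }
  if (!length(v)) stop_data_quality("All analysis channels undefined; no montage average.")
  mean(v)
}

#' Extract the six spectral features of one session
#'
#' Welch PSD of the kept epochs, relative power over 2-80 Hz, the five
#' relative band powers and the individual peak frequency per channel, then
#' averaged over the analysis montage — one long-format feature row per
#' feature.
#'
#' @param es An `eeg_epochs` object (preprocessed).
#' @param montage The analysis `eeg_montage`.
#' @param scheme A [band_scheme()].
#' @return A 6-row tibble with columns `subject_id`, `session_id`,
#'   `feature_name`, `value`.
#' @export
compute_features <- function(es, montage, scheme = band_scheme()) {
  ps <- relative_power(welch_psd(es, window_s = 2, overlap = 0.5),
    total_range = scheme$total_range
  )
  rbp <- band_powers(ps, scheme)
  ipf <- individual_peak_frequency(ps)
  vals <- c(
    vapply(rownames(rbp), function(b) {
      montage_average(setNames(rbp[b, ], colnames(rbp)), montage)
    }, 0),
    ipf = montage_average(ipf, montage)
  )
  tibble::tibble(
    subject_id = es$subject_id,
    session_id = es$session_id,
    feature_name = c(paste0("rbp_", rownames(rbp)), "ipf"),
    value = unname(vals)
  )
}
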