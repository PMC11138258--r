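#' Filter specification for the preprocessing chain
#'
#' The conditioning chain is a 2 Hz highpass, an 80 Hz lowpass, and a
#' 55-65 Hz mains bandstop repeated at every harmonic (115-125, 175-185, ...)
#' up to the Nyquist frequency of the original sampling rate. All stages are
#' symmetric windowed-sinc FIR kernels (Blackman window) applied once, so the
#' overall response is exactly zero-phase. Transition widths are 25% of the
#' highpass/lowpass cutoff and 25% of the stop bandwidth for each bandstop
#' edge.
#'
#' @param fs Sampling rate of the data the filter will be applied to (Hz).
#' @param highpass_hz,lowpass_hz Passband edges (Hz).
#' @param bandstop_base Mains stopband `(low, high)` in Hz; harmonics are
#'   added automatically up to Nyquist.
#' @param harmonics Add harmonic stopbands (`TRUE` by default).
#' @return A `filter_spec` list containing the composed symmetric kernel.
#' @export
filter_spec <- function(fs, highpass_hz = 2, lowpass_hz = 80,
                        bandstop_base = c(55, 65), harmonics = TRUE) {
  assert_scalar_number(fs, "fs", lower = 1)
  assert_scalar_number(highpass_hz, "highpass_hz", lower = 0)
  assert_scalar_number(lowpass_hz, "lowpass_hz", lower = highpass_hz + 1e-9)
  nyq <- fs / 2
  if (nyq <= lowpass_hz) {
    stop_config(sprintf(
      "Sampling rate %g Hz is too low for an %g Hz lowpass.", fs, lowpass_hz
    ))
  }
  stops <- list()
  if (!is.null(bandstop_base)) {
    base_lo <- bandstop_base[1]
    base_hi <- bandstop_base[2]
    center <- (base_lo + base_hi) / 2
    width <- base_hi - base_lo
    h_max <- if (harmonics) floor((nyq - width / 2) / center) else 1L
    for (h in seq_len(max(h_max, 0L))) {
      lo <- h * center - width / 2
      hi <- h * center + width / 2
      if (lo > 0 && hi < nyq) stops[[length(stops) + 1L]] <- c(lo, hi)
    }
  }

  kernels <- list(
    fir_highpass(highpass_hz, 0.25 * highpass_hz, fs),
    fir_lowpass(lowpass_hz, 0.25 * lowpass_hz, fs)
  )
  for (s in stops) {
    trans <- 0.25 * (s[2] - s[1])
    kernels[[length(kernels) + 1L]] <- fir_bandstop(s[1], s[2], trans, fs)
  }
  kern <- Reduce(conv_full, kernels)

  structure(
    list(
      fs = fs, highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
      bandstop = stops, zero_phase = TRUE, kernel = kern
    ),
    class = "filter_spec"
  )
}

blackman_win <- function(n) {
  i <- seq_len(n) - 1
  0.42 - 0.5 * cos(2 * pi * i / (n - 1)) + 0.08 * cos(4 * pi * i / (n - 1))
}

# Windowed-sinc lowpass; `fc` is the -6 dB cutoff, `trans` the transition
# width (Blackman window: ~5.5/N normalized transition, ~74 dB stopband).
fir_lowpass <- function(fc, trans, fs) {
  n <- ceiling(5.5 * fs / trans)
  if (n %% 2 == 0) n <- n + 1
  m <- (n - 1) / 2
  t <- seq(-m, m)
  h <- 2 * fc / fs * sinc(2 * fc / fs * t) * blackman_win(n)
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

unit_impulse <- function(n) {
  d <- numeric(n)
  d[(n + 1) / 2] <- 1
  d
}

fir_highpass <- function(fc, trans, fs) {
  h <- fir_lowpass(fc, trans, fs)
  unit_impulse(length(h)) - h # spectral inversion
}

fir_bandstop <- function(f1, f2, trans, fs) {
  lp <- fir_lowpass(f1, trans, fs)
  hp <- fir_highpass(f2, trans, fs)
  n <- max(length(lp), length(hp))
  pad <- function(h) {
    k <- (n - length(h)) / 2
    c(numeric(k), h, numeric(k))
  }
  pad(lp) + pad(hp) # parallel low + high passes reject the band
}

conv_full <- function(a, b) {
  n <- length(a) + length(b) - 1
  nf <- stats::nextn(n, 2)
  re <- Re(fft(fft(c(a, numeric(nf - length(a)))) *
    fft(c(b, numeric(nf - length(b)))), inverse = TRUE)) / nf
  re[seq_len(n)]
}

# Odd (antisymmetric) extension by `p` samples on each side: continuous in
# value and first derivative at the boundary, which keeps long zero-phase
# kernels from ringing at the record edges. Falls back to tiled even
# reflection when the pad is longer than the signal.
pad_reflect <- function(x, p) {
  n <- length(x)
  if (p <= n - 1) {
    left <- 2 * x[1] - x[(p + 1):2]
    right <- 2 * x[n] - x[(n - 1):(n - p)]
    return(c(left, x, right))
  }
  tile <- c(x, rev(x))
  idx_left <- ((-(p:1)) %% (2 * n)) + 1
  idx_right <- ((n + seq_len(p) - 1) %% (2 * n)) + 1
  c(tile[idx_left], x, tile[idx_right])
}

filter_apply_kernel <- function(x, kern) {
  p <- (length(kern) - 1) / 2
  xp <- pad_reflect(x, p)
  n <- length(xp) + length(kern) - 1
  nf <- stats::nextn(n, 2)
  y <- Re(fft(fft(c(xp, numeric(nf - length(xp)))) *
    fft(c(kern, numeric(nf - length(kern)))), inverse = TRUE)) / nf
  y[(2 * p + 1):(2 * p + length(x))]
}

#' Amplitude response of a designed filter chain
#'
#' Evaluates the magnitude of the composed kernel's frequency response at
#' the requested frequencies.
#'
#' @param fspec A [filter_spec()].
#' @param freqs Frequencies in Hz.
#' @return Numeric vector of linear amplitude gains.
#' @export
filter_response <- function(fspec, freqs) {
  stopifnot(inherits(fspec, "filter_spec"))
  tt <- (seq_along(fspec$kernel) - 1) / fspec$fs
  vapply(freqs, function(f) {
    Mod(sum(fspec$kernel * exp(-2i * pi * f * tt)))
  }, 0)
}

#' Apply the zero-phase filter chain to a recording
#'
#' @param rec An [eeg_recording()].
#' @param fspec A [filter_spec()] built for the recording's sampling rate.
#' @return The filtered [eeg_recording()].
#' @export
apply_filters <- function(rec, fspec = filter_spec(rec$fs)) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(fspec, "filter_spec"))
  if (abs(fspec$fs - rec$fs) > 1e-9) {
    stop_config("Filter was designed for a different sampling rate.")
  }
  out <- rec
  out$data <- t(apply(rec$data, 1, filter_apply_kernel, kern = fspec$kernel))
  rownames(out$data) <- rec$channel_labels
  out
}

#' Segment a recording into fixed-length epochs
#'
#' Cuts the recording into consecutive non-overlapping epochs of
#' `epoch_length_s` seconds; a trailing partial epoch is discarded. The
#' result is an `eeg_epochs` object holding an epochs x channels x samples
#' array, a `kept_mask` (all `TRUE` initially; updated by
#' [reject_epochs()]), and the list of interpolated channels.
#'
#' @param rec An [eeg_recording()].
#' @param epoch_length_s Epoch length in seconds (default 2).
#' @return An `eeg_epochs` object.
#' @export
segment_epochs <- function(rec, epoch_length_s = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  assert_scalar_number(epoch_length_s, "epoch_length_s", lower = .Machine$double.eps)
  spe <- round(epoch_length_s * rec$fs)
  if (abs(spe - epoch_length_s * rec$fs) > 1e-9) {
    stop_validation("`epoch_length_s * fs` must be an integer sample count.")
  }
  n_ep <- ncol(rec$data) %/% spe
  if (n_ep < 1) {
    stop_validation(sprintf(
      "Recording (%.2f s) is shorter than one %g s epoch.",
      ncol(rec$data) / rec$fs, epoch_length_s
    ))
  }
  ep <- array(NA_real_, dim = c(n_ep, nrow(rec$data), spe))
  for (e in seq_len(n_ep)) {
    ep[e, , ] <- rec$data[, ((e - 1) * spe + 1):(e * spe)]
  }
  structure(
    list(
      epochs = ep, fs = rec$fs, epoch_length_s = epoch_length_s,
      kept_mask = rep(TRUE, n_ep),
      channel_labels = rec$channel_labels,
      interpolated_channels = character(0),
      subject_id = rec$subject_id, session_id = rec$session_id
    ),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf(
    "<eeg_epochs> %d x %g s epochs (%d kept), %d channels @ %g Hz\n",
    dim(x$epochs)[1], x$epoch_length_s, sum(x$kept_mask),
    dim(x$epochs)[2], x$fs
  ))
  invisible(x)
}

#' Reject artifact epochs by amplitude and robust variance
#'
#' An epoch is dropped when any analysis channel's half peak-to-peak
#' amplitude exceeds `abs_thresh_uv` microvolts, or when the epoch's log
#' total variance lies more than `z_thresh` robust z-units (median/MAD)
#' above the across-epoch median. This deterministic screen stands in for
#' manual artifact inspection.
#'
#' @param es An `eeg_epochs` object.
#' @param abs_thresh_uv Amplitude threshold in microvolts (half peak-to-peak).
#' @param z_thresh Robust z threshold on log total epoch variance.
#' @param montage Optional `eeg_montage`; when given, amplitude screening is
#'   restricted to non-excluded channels.
#' @return The `eeg_epochs` with an updated `kept_mask` (order preserved).
#' @export
reject_epochs <- function(es, abs_thresh_uv = 150, z_thresh = 4, montage = NULL) {
  stopifnot(inherits(es, "eeg_epochs"))
  assert_scalar_number(abs_thresh_uv, "abs_thresh_uv", lower = 0)
  assert_scalar_number(z_thresh, "z_thresh", lower = 0)
  n_ep <- dim(es$epochs)[1]
  ch_idx <- seq_len(dim(es$epochs)[2])
  if (!is.null(montage)) {
    keep_ch <- es$channel_labels %in% analysis_channels(montage)
    if (any(keep_ch)) ch_idx <- which(keep_ch)
  }

  half_p2p <- vapply(seq_len(n_ep), function(e) {
    x <- matrix(es$epochs[e, ch_idx, ], nrow = length(ch_idx))
    max((apply(x, 1, max) - apply(x, 1, min)) / 2)
  }, 0)
  amp_bad <- half_p2p > abs_thresh_uv

  log_var <- vapply(seq_len(n_ep), function(e) {
    x <- matrix(es$epochs[e, ch_idx, ], nrow = length(ch_idx))
    log(max(sum(apply(x, 1, var)), .Machine$double.xmin))
  }, 0)
  med <- median(log_var)
  s <- mad(log_var)
  z <- if (s > 0) (log_var - med) / s else rep(0, n_ep)
  var_bad <- z > z_thresh

  # degenerate threshold: abs_thresh_uv = 0 rejects every non-constant epoch
  if (abs_thresh_uv == 0) amp_bad <- half_p2p >= 0

  kept <- es$kept_mask & !amp_bad & !var_bad
  if (!any(kept)) {
    stop_data_quality(
      sprintf(
        "All %d epochs rejected (%d amplitude, %d variance).",
        n_ep, sum(amp_bad), sum(var_bad)
      ),
      n_epochs = n_ep, n_amplitude = sum(amp_bad), n_variance = sum(var_bad)
    )
  }
  es$kept_mask <- kept
  es
}

#' Detect bad channels by robust variance statistics
#'
#' Flags channels that are exactly flat, or whose log variance over the
#' recording lies more than `z_thresh` robust z-units from the median. At
#' most `floor(max_frac * n_channels)` labels are returned (worst first),
#' mirroring a 5%-of-channels interpolation cap; a warning reports any
#' channels beyond the cap.
#'
#' @param es An `eeg_epochs` object.
#' @param z_thresh Robust z threshold on per-channel log variance.
#' @param max_frac Maximum fraction of channels returned.
#' @return Character vector of bad channel labels (possibly empty).
#' @export
detect_bad_channels <- function(es, z_thresh = 5, max_frac = 0.05) {
  stopifnot(inherits(es, "eeg_epochs"))
  n_ch <- dim(es$epochs)[2]
  if (n_ch < 2) stop_validation("Need at least 2 channels.")
  ch_var <- vapply(seq_len(n_ch), function(c) {
    var(as.vector(es$epochs[es$kept_mask, c, ]))
  }, 0)
  flat <- ch_var == 0
  lv <- log(pmax(ch_var, .Machine$double.xmin))
  med <- median(lv[!flat])
  s <- mad(lv[!flat])
  z <- if (is.finite(s) && s > 0) abs(lv - med) / s else rep(0, n_ch)
  z[flat] <- Inf
  # also require a >= 4x variance ratio so that near-homogeneous arrays
  # (tiny MAD) do not produce spurious flags
  bad <- which(flat | (z > z_thresh & abs(lv - med) > log(4)))
  if (!length(bad)) {
    return(character(0))
  }
  bad <- bad[order(-z[bad])]
  cap <- floor(max_frac * n_ch)
  if (length(bad) > cap) {
    warn(sprintf(
      "%d channels flagged bad but only %d interpolable under the %.0f%% cap.",
      length(bad), cap, 100 * max_frac
    ))
    bad <- bad[seq_len(cap)]
  }
  es$channel_labels[bad]
}

# Perrin-style spherical-spline g function: truncated Legendre series
# g(x) = (1/4pi) * sum_{l=1}^{L} (2l+1) / (l (l+1))^m * P_l(x)
spline_g <- function(x, m = 4, n_legendre = 7) {
  x <- pmin(pmax(x, -1), 1)
  p_prev <- rep(1, length(x)) # P_0
  p_cur <- x # P_1
  acc <- (2 * 1 + 1) / (1 * 2)^m * p_cur
  if (n_legendre >= 2) {
    for (l in 2:n_legendre) {
      p_next <- ((2 * l - 1) * x * p_cur - (l - 1) * p_prev) / l
      acc <- acc + (2 * l + 1) / (l * (l + 1))^m * p_next
      p_prev <- p_cur
      p_cur <- p_next
    }
  }
  acc / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces each bad channel's samples with the spherical-spline estimate
#' computed from the good channels (Legendre series truncated at
#' `n_legendre` terms, spline order `m`, ridge regularization `lambda` on
#' the spline system). Good channels are untouched; the epoch count and
#' length are preserved; interpolated labels are recorded on the object.
#'
#' @param es An `eeg_epochs` object.
#' @param bad Character vector of channel labels to interpolate.
#' @param montage An `eeg_montage` covering all channels of `es`.
#' @param m Spline order (stiffness) of the g-function.
#' @param n_legendre Number of Legendre terms retained.
#' @param lambda Ridge regularization added to the spline system diagonal.
#' @return The `eeg_epochs` with bad channels replaced.
#' @export
spherical_spline_interpolate <- function(es, bad, montage, m = 4,
                                         n_legendre = 7, lambda = 1e-5) {
  stopifnot(inherits(es, "eeg_epochs"), inherits(montage, "eeg_montage"))
  if (!length(bad)) {
    return(es)
  }
  unknown <- setdiff(bad, es$channel_labels)
  if (length(unknown)) {
    stop_validation(paste0("Unknown channel label(s): ", paste(unknown, collapse = ", ")))
  }
  if (!all(es$channel_labels %in% montage$label)) {
    stop_validation("Montage does not cover all recording channels.")
  }
  pos <- as.matrix(montage[match(es$channel_labels, montage$label), c("x", "y", "z")])
  bad_idx <- match(bad, es$channel_labels)
  good_idx <- setdiff(seq_along(es$channel_labels), bad_idx)
  if (length(good_idx) < 4) {
    stop_validation("Spherical-spline interpolation needs at least 4 good channels.")
  }

  cosang <- tcrossprod(pos) # cosine of angular distance on the unit sphere
  g_gg <- spline_g(cosang[good_idx, good_idx, drop = FALSE], m, n_legendre)
  g_bg <- spline_g(cosang[bad_idx, good_idx, drop = FALSE], m, n_legendre)
  ng <- length(good_idx)
  a <- rbind(
    cbind(g_gg + diag(lambda, ng), rep(1, ng)),
    c(rep(1, ng), 0)
  )
  # interpolant = [g_bg 1] A^{-1} [v; 0]; precompute the mapping matrix
  map <- t(solve(t(a), t(cbind(g_bg, rep(1, length(bad_idx))))))[, seq_len(ng), drop = FALSE]

  n_ep <- dim(es$epochs)[1]
  spe <- dim(es$epochs)[3]
  for (e in seq_len(n_ep)) {
    v <- matrix(es$epochs[e, good_idx, ], nrow = ng)
    es$epochs[e, bad_idx, ] <- map %*% v
  }
  es$interpolated_channels <- union(es$interpolated_channels, bad)
  es
}

#' Run the whole preprocessing chain on one recording
#'
#' Filter -> segment into 2 s epochs -> detect bad channels -> spherical
#' spline interpolation -> artifact-epoch rejection, returning the cleaned
#' epochs plus an accounting row (epochs kept, channels interpolated).
#'
#' @param rec An [eeg_recording()].
#' @param montage The analysis `eeg_montage`.
#' @param fspec Optional [filter_spec()]; defaults to the standard chain at
#'   the recording's sampling rate.
#' @param epoch_length_s Epoch length (s).
#' @param abs_thresh_uv,z_thresh_epoch Epoch rejection thresholds.
#' @param z_thresh_channel,max_bad_frac Bad-channel detection parameters.
#' @return A list with `epochs` (`eeg_epochs`) and `report` (one-row tibble).
#' @export
preprocess_recording <- function(rec, montage,
                                 fspec = filter_spec(rec$fs),
                                 epoch_length_s = 2,
                                 abs_thresh_uv = 150, z_thresh_epoch = 4,
                                 z_thresh_channel = 5, max_bad_frac = 0.05) {
  filtered <- apply_filters(rec, fspec)
  es <- segment_epochs(filtered, epoch_length_s)
  bad <- detect_bad_channels(es, z_thresh_channel, max_bad_frac)
  if (length(bad)) {
    es <- spherical_spline_interpolate(es, bad, montage)
  }
  es <- reject_epochs(es, abs_thresh_uv, z_thresh_epoch, montage)
  report <- tibble::tibble(
    subject_id = rec$subject_id, session_id = rec$session_id,
    n_epochs = dim(es$epochs)[1], n_kept = sum(es$kept_mask),
    n_interpolated = length(es$interpolated_channels),
    interpolated = paste(es$interpolated_channels, collapse = ";")
  )
  list(epochs = es, report = report)
}
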