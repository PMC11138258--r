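#' Specify a synthetic repeated-session EEG study
#'
#' Builds the full parameter set for the synthetic-data generator. The
#' generator emulates a test-retest resting-state EEG study: each subject is
#' recorded in `sessions_per_subject` sessions; each recording is a
#' multichannel mixture of a 1/f^chi aperiodic background, five band-limited
#' noise components whose per-band amplitudes follow a subject/session/error
#' variance decomposition on the log scale, and a narrowband alpha
#' oscillation at a subject-specific peak frequency. Because the variance
#' components are chosen from per-feature target ICCs via
#' [variance_components_for_icc()], the true reliability of every feature is
#' known, which is what makes parameter-recovery testing of the downstream
#' ICC pipeline possible.
#'
#' Defaults follow the emulated acquisition: 128 channels at 1000 Hz for
#' 300 s, alpha peak 10 +/- 1 Hz, and same-day target ICCs
#' (delta .81, theta .875, alpha .959, beta .84, gamma .814, IPF .847).
#'
#' @param n_subjects,sessions_per_subject Study size.
#' @param fs Sampling rate (Hz). `fs * duration` must be an integer.
#' @param duration Recording length in seconds.
#' @param n_channels Number of electrodes.
#' @param aperiodic_exponent_mean,aperiodic_exponent_sd Mean/SD across
#'   subjects of the aperiodic 1/f exponent chi (power ~ 1/f^chi).
#' @param alpha_peak_freq_mean,alpha_peak_freq_sd Between-subject mean/SD of
#'   the alpha peak frequency (Hz); draws are truncated to \[8, 12.5\].
#' @param band_log_amp_mean Named vector (delta..gamma) of mean log band
#'   amplitudes; `exp()` of a realized value is the band-limited component's
#'   standard deviation in microvolts.
#' @param icc_targets Named vector of target true ICCs for the six features.
#' @param band_log_amp_var Total variance of each band's log amplitude.
#' @param session_share Fraction of the non-subject variance assigned to the
#'   session (visit) component; the rest is residual.
#' @param alpha_osc_gain Amplitude of the alpha oscillation relative to the
#'   alpha band-noise standard deviation.
#' @param background_rms Standard deviation (microvolts) of the aperiodic
#'   background component.
#' @param line_noise_60hz,n_bad_channels,blink_rate Artifact options: add a
#'   60 Hz mains sinusoid; zero out this many channels (flat bad channels);
#'   blink-like low-frequency transients per minute on frontal channels.
#' @param interval_design `"same_day"` (all sessions labelled `same_day`) or
#'   `"longitudinal"` (session 1 is `baseline`, later sessions labelled by
#'   `interval_weeks`).
#' @param interval_weeks Labels for follow-up sessions in the longitudinal
#'   design.
#' @param seed Master seed; all per-subject/per-session random streams are
#'   derived from it by a counter scheme, so enlarging the study never
#'   perturbs already-generated subjects.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_subjects = 30,
                            sessions_per_subject = 2,
                            fs = 1000,
                            duration = 300,
                            n_channels = 128,
                            aperiodic_exponent_mean = 1.5,
                            aperiodic_exponent_sd = 0.15,
                            alpha_peak_freq_mean = 10,
                            alpha_peak_freq_sd = 1,
                            band_log_amp_mean = log(c(
                              delta = 10, theta = 6, alpha = 8,
                              beta = 4, gamma = 2
                            )),
                            icc_targets = c(
                              rbp_delta = 0.81, rbp_theta = 0.875,
                              rbp_alpha = 0.959, rbp_beta = 0.84,
                              rbp_gamma = 0.814, ipf = 0.847
                            ),
                            band_log_amp_var = 0.09,
                            session_share = 0.3,
                            alpha_osc_gain = 2,
                            background_rms = 4,
                            line_noise_60hz = FALSE,
                            n_bad_channels = 0,
                            blink_rate = 0,
                            interval_design = c("same_day", "longitudinal"),
                            interval_weeks = c("2wk", "4wk", "6wk"),
                            seed = 1L) {
  n_subjects <- assert_count(n_subjects, "n_subjects")
  sessions_per_subject <- assert_count(sessions_per_subject, "sessions_per_subject")
  assert_scalar_number(fs, "fs", lower = 1)
  assert_scalar_number(duration, "duration", lower = .Machine$double.eps)
  if (abs(fs * duration - round(fs * duration)) > 1e-9) {
    stop_config("`fs * duration` must be an integer number of samples.")
  }
  n_channels <- assert_count(n_channels, "n_channels", lower = 1)
  assert_scalar_number(alpha_peak_freq_mean, "alpha_peak_freq_mean", 8, 12.5)
  assert_scalar_number(alpha_peak_freq_sd, "alpha_peak_freq_sd", 0)
  assert_scalar_number(band_log_amp_var, "band_log_amp_var", 0)
  assert_scalar_number(session_share, "session_share", 0, 1)
  if (!all(names(icc_targets) %in% feature_levels()) ||
    length(icc_targets) != 6L) {
    stop_config("`icc_targets` must name all six features.")
  }
  if (any(icc_targets < 0 | icc_targets > 1)) {
    stop_config("`icc_targets` must lie in [0, 1].")
  }
  n_bad_channels <- assert_count(n_bad_channels, "n_bad_channels", lower = 0)
  assert_scalar_number(blink_rate, "blink_rate", 0)
  interval_design <- match.arg(interval_design)

  bands <- c("delta", "theta", "alpha", "beta", "gamma")
  vc <- lapply(setNames(bands, bands), function(b) {
    if (band_log_amp_var == 0) {
      return(c(subject = 0, session = 0, error = 0)) # degenerate: no variability
    }
    variance_components_for_icc(
      icc_targets[[paste0("rbp_", b)]], band_log_amp_var, session_share
    )
  })
  # IPF: between-subject variance is alpha_peak_freq_sd^2; the within
  # (session + residual) jitter variance follows from the target ICC.
  ipf_icc <- icc_targets[["ipf"]]
  ipf_within_var <- if (ipf_icc >= 1) 0 else alpha_peak_freq_sd^2 * (1 - ipf_icc) / max(ipf_icc, 1e-12)

  structure(
    list(
      n_subjects = n_subjects, sessions_per_subject = sessions_per_subject,
      fs = fs, duration = duration, n_channels = n_channels,
      aperiodic_exponent_mean = aperiodic_exponent_mean,
      aperiodic_exponent_sd = aperiodic_exponent_sd,
      alpha_peak_freq_mean = alpha_peak_freq_mean,
      alpha_peak_freq_sd = alpha_peak_freq_sd,
      band_log_amp_mean = band_log_amp_mean,
      icc_targets = icc_targets,
      band_log_amp_var = band_log_amp_var,
      session_share = session_share,
      variance_components = vc,
      ipf_within_var = ipf_within_var,
      alpha_osc_gain = alpha_osc_gain,
      background_rms = background_rms,
      line_noise_60hz = isTRUE(line_noise_60hz),
      n_bad_channels = n_bad_channels,
      blink_rate = blink_rate,
      interval_design = interval_design,
      interval_weeks = interval_weeks,
      seed = as.integer(seed)
    ),
    class = "simulation_spec"
  )
}

#' Split a total variance into ICC-consistent components
#'
#' Given a target intraclass correlation (ratio of between-subject variance
#' to total variance), returns the `(subject, session, error)` variance
#' triple: the subject component is `target_icc * total_var` and the
#' remainder is split between session and residual by `session_share`.
#'
#' @param target_icc Target ICC in \[0, 1\].
#' @param total_var Total variance (> 0).
#' @param session_share Fraction of the non-subject variance assigned to the
#'   session component, in \[0, 1\].
#' @return Named numeric vector `c(subject=, session=, error=)` summing to
#'   `total_var`.
#' @examples
#' variance_components_for_icc(0.8, 1, 0.25) # c(0.8, 0.05, 0.15)
#' @export
variance_components_for_icc <- function(target_icc, total_var, session_share) {
  assert_scalar_number(target_icc, "target_icc", 0, 1)
  assert_scalar_number(total_var, "total_var", lower = .Machine$double.eps)
  assert_scalar_number(session_share, "session_share", 0, 1)
  s2_subject <- target_icc * total_var
  rest <- total_var - s2_subject
  c(
    subject = s2_subject,
    session = session_share * rest,
    error = (1 - session_share) * rest
  )
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (sd == 0) {
    return(min(max(mean, lo), hi))
  }
  for (i in 1:1000) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) {
      return(x)
    }
  }
  min(max(mean, lo), hi)
}

#' Draw latent subject/session profiles
#'
#' Realizes the latent layer of the generative model: per-subject band
#' log-amplitude effects, per-session offsets and residuals (variances taken
#' from the spec's per-feature components), a per-subject aperiodic exponent,
#' and a per-subject alpha peak frequency (truncated normal on \[8, 12.5\] Hz)
#' with optional per-session jitter. Fully determined by the spec's seed.
#'
#' @param spec A [simulation_spec()].
#' @return A `ground_truth` list with elements `log_amp` (subjects x sessions
#'   x bands array), `peak_freq` (subjects x sessions), `chi` (per subject),
#'   and `true_icc` (named per-feature latent ICC).
#' @export
sample_subject_profiles <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n_subjects
  k <- spec$sessions_per_subject
  bands <- names(spec$band_log_amp_mean)
  log_amp <- array(NA_real_,
    dim = c(n, k, length(bands)),
    dimnames = list(NULL, NULL, bands)
  )
  peak_freq <- matrix(NA_real_, n, k)
  chi <- numeric(n)

  for (i in seq_len(n)) {
    with_seed_(child_seed(spec$seed, 1L, i), {
      subj_eff <- vapply(bands, function(b) {
        rnorm(1, 0, sqrt(spec$variance_components[[b]][["subject"]]))
      }, 0)
      chi[i] <- rnorm(1, spec$aperiodic_exponent_mean, spec$aperiodic_exponent_sd)
      pf <- rtruncnorm1(spec$alpha_peak_freq_mean, spec$alpha_peak_freq_sd, 8, 12.5)
      for (j in seq_len(k)) {
        with_seed_(child_seed(spec$seed, 1L, i, j), {
          for (b in bands) {
            vcb <- spec$variance_components[[b]]
            log_amp[i, j, b] <- spec$band_log_amp_mean[[b]] + subj_eff[[b]] +
              rnorm(1, 0, sqrt(vcb[["session"]])) +
              rnorm(1, 0, sqrt(vcb[["error"]]))
          }
          jit <- if (spec$ipf_within_var > 0) rnorm(1, 0, sqrt(spec$ipf_within_var)) else 0
          peak_freq[i, j] <- min(max(pf + jit, 8), 12.5)
        })
      }
    })
  }

  true_icc <- c(
    vapply(setNames(bands, paste0("rbp_", bands)), function(b) {
      vcb <- spec$variance_components[[b]]
      tot <- sum(vcb)
      if (tot == 0) 1 else vcb[["subject"]] / tot
    }, 0),
    ipf = if (spec$alpha_peak_freq_sd == 0 && spec$ipf_within_var == 0) {
      1
    } else {
      spec$alpha_peak_freq_sd^2 / (spec$alpha_peak_freq_sd^2 + spec$ipf_within_var)
    }
  )

  structure(
    list(log_amp = log_amp, peak_freq = peak_freq, chi = chi, true_icc = true_icc),
    class = "ground_truth"
  )
}

band_edges <- function() {
  list(
    delta = c(2, 3.5), theta = c(4, 7.5), alpha = c(8, 12.5),
    beta = c(13, 30), gamma = c(30, 80)
  )
}

# Real Gaussian noise whose spectrum is confined to the given gain profile,
# built by drawing a complex Gaussian spectrum and taking the real part of
# its inverse DFT: exact band control, no filter ringing.
shaped_noise <- function(n, n_ch, fs, gain) {
  z <- matrix(complex(
    real = rnorm(n * n_ch),
    imaginary = rnorm(n * n_ch)
  ), n, n_ch)
  z <- z * gain
  x <- Re(mvfft(z, inverse = TRUE)) / n
  x
}

freq_grid_full <- function(n, fs) {
  f <- (seq_len(n) - 1) * fs / n
  pmin(f, fs - f) # aliased (two-sided) frequency magnitude
}

rescale_cols <- function(x, target_sd) {
  s <- apply(x, 2, sd)
  s[s == 0] <- 1
  sweep(x, 2, target_sd / s, "*")
}

#' Synthesize one subject-session EEG recording
#'
#' Builds the channels x samples signal for one cell of the design: aperiodic
#' 1/f^chi background + five band-limited Gaussian components with per-band
#' standard deviations `exp(log_amp)` + an alpha sinusoid at the subject's
#' peak frequency, plus optional 60 Hz line noise, flat bad channels, and
#' blink-like frontal transients. Deterministic given the spec seed and the
#' (subject, session) indices.
#'
#' @param truth A `ground_truth` from [sample_subject_profiles()].
#' @param subject,session Indices into the design.
#' @param spec The [simulation_spec()].
#' @param montage Optional `eeg_montage` supplying channel labels (and
#'   frontal positions for blink placement). Defaults to generic labels.
#' @return An [eeg_recording()].
#' @export
synthesize_session <- function(truth, subject, session, spec, montage = NULL) {
  stopifnot(inherits(spec, "simulation_spec"), inherits(truth, "ground_truth"))
  subject <- assert_count(subject, "subject")
  session <- assert_count(session, "session")
  n <- as.integer(round(spec$fs * spec$duration))
  n_ch <- spec$n_channels
  if (!is.null(montage) && nrow(montage) != n_ch) {
    stop_validation("Montage size must match `spec$n_channels`.")
  }
  labels <- if (is.null(montage)) paste0("E", seq_len(n_ch)) else montage$label

  f <- freq_grid_full(n, spec$fs)
  edges <- band_edges()

  x <- with_seed_(child_seed(spec$seed, 2L, subject, session), {
    # aperiodic background: amplitude ~ f^(-chi/2) above 0.5 Hz
    chi <- truth$chi[subject]
    gain_bg <- ifelse(f >= 0.5, f^(-chi / 2), 0)
    sig <- rescale_cols(
      shaped_noise(n, n_ch, spec$fs, gain_bg),
      rep(spec$background_rms, n_ch)
    )
    for (b in names(edges)) {
      mask <- as.numeric(f >= edges[[b]][1] & f <= edges[[b]][2])
      amp <- exp(truth$log_amp[subject, session, b])
      sig <- sig + rescale_cols(shaped_noise(n, n_ch, spec$fs, mask), rep(amp, n_ch))
    }
    # alpha oscillation at the subject's peak frequency
    fp <- truth$peak_freq[subject, session]
    a_amp <- spec$alpha_osc_gain * exp(truth$log_amp[subject, session, "alpha"])
    t <- (seq_len(n) - 1) / spec$fs
    ph <- runif(n_ch, 0, 2 * pi)
    sig <- sig + a_amp * sin(outer(2 * pi * fp * t, ph, "+"))
    if (spec$line_noise_60hz && spec$fs > 120) {
      sig <- sig + 30 * sin(2 * pi * 60 * t)
    }
    if (spec$blink_rate > 0) {
      frontal <- if (!is.null(montage)) {
        which(montage$y > 0.5)
      } else {
        seq_len(max(1L, n_ch %/% 8L))
      }
      n_blinks <- rpois(1, spec$blink_rate * spec$duration / 60)
      blink_len <- round(0.4 * spec$fs)
      shape <- 150 * sin(pi * seq_len(blink_len) / blink_len)^2
      if (n_blinks > 0 && n > blink_len) {
        starts <- sort(sample.int(n - blink_len, n_blinks))
        for (s0 in starts) {
          sig[s0:(s0 + blink_len - 1), frontal] <-
            sig[s0:(s0 + blink_len - 1), frontal] + shape
        }
      }
    }
    if (spec$n_bad_channels > 0) {
      bad <- sample.int(n_ch, min(spec$n_bad_channels, n_ch))
      sig[, bad] <- 0
    }
    sig
  })

  eeg_recording(
    t(x), spec$fs,
    channel_labels = labels,
    subject_id = sprintf("S%03d", subject),
    session_id = sprintf("V%d", session),
    session_datetime = session_datetime_for(spec, subject, session)
  )
}

session_datetime_for <- function(spec, subject, session) {
  base <- as.POSIXct("2024-01-08 09:00:00", tz = "UTC") + (subject - 1) * 86400
  if (spec$interval_design == "same_day") {
    base + (session - 1) * 5 * 3600 # repeats 4-6 h apart within the day
  } else {
    weeks <- c(0, suppressWarnings(as.numeric(sub("wk", "", spec$interval_weeks))))
    weeks[is.na(weeks)] <- seq_along(weeks[is.na(weeks)]) * 2
    base + weeks[session] * 7 * 86400
  }
}

interval_label_for <- function(spec, session) {
  if (spec$interval_design == "same_day") {
    "same_day"
  } else if (session == 1L) {
    "baseline"
  } else {
    spec$interval_weeks[session - 1L]
  }
}

#' Generate a complete synthetic test-retest dataset
#'
#' Realizes the latent profiles and synthesizes every subject-session
#' recording, together with the session table (interval labels per the
#' spec's interval design) and the ground truth needed for parameter
#' recovery. Optionally writes EDF files plus CSV side-cars to `out_dir`.
#'
#' @inheritParams synthesize_session
#' @param out_dir Optional directory for EDF + CSV output.
#' @return A list with `recordings` (list of [eeg_recording()]), `sessions`
#'   (session table), `truth` (`ground_truth`) and `montage`.
#' @export
generate_dataset <- function(spec, montage = NULL, out_dir = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (spec$interval_design == "longitudinal" &&
    spec$sessions_per_subject != length(spec$interval_weeks) + 1L) {
    stop_config("Longitudinal design needs sessions_per_subject = length(interval_weeks) + 1.")
  }
  if (is.null(montage)) {
    montage <- if (spec$n_channels == 128) {
      default_montage()
    } else {
      synthetic_montage(spec$n_channels)
    }
  }
  truth <- sample_subject_profiles(spec)
  recs <- list()
  rows <- list()
  for (i in seq_len(spec$n_subjects)) {
    for (j in seq_len(spec$sessions_per_subject)) {
      rec <- synthesize_session(truth, i, j, spec, montage)
      recs[[length(recs) + 1L]] <- rec
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = rec$subject_id, session_id = rec$session_id,
        session_datetime = rec$session_datetime,
        interval_label = interval_label_for(spec, j)
      )
    }
  }
  sessions <- validate_session_table(dplyr::bind_rows(rows))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (rec in recs) {
      write_edf(rec, file.path(out_dir, paste0(rec$subject_id, "_", rec$session_id, ".edf")))
    }
    write_session_table(sessions, file.path(out_dir, "sessions.csv"))
    write_ground_truth(truth, file.path(out_dir))
  }

  list(recordings = recs, sessions = sessions, truth = truth, montage = montage)
}

write_ground_truth <- function(truth, dir) {
  icc <- tibble::tibble(
    feature_name = names(truth$true_icc),
    true_icc = unname(truth$true_icc)
  )
  readr::write_csv(icc, file.path(dir, "ground_truth_icc.csv"))
  n <- dim(truth$log_amp)[1]
  k <- dim(truth$log_amp)[2]
  bands <- dimnames(truth$log_amp)[[3]]
  long <- tidyr::expand_grid(subject = seq_len(n), session = seq_len(k))
  for (b in bands) {
    long[[paste0("log_amp_", b)]] <-
      purrr::map2_dbl(long$subject, long$session, ~ truth$log_amp[.x, .y, b])
  }
  long$peak_freq <- purrr::map2_dbl(long$subject, long$session, ~ truth$peak_freq[.x, .y])
  readr::write_csv(long, file.path(dir, "ground_truth_sessions.csv"))
  invisible(dir)
}

#' Simulate paired measurements for one feature
#'
#' Draws an `n x k` matrix directly from the latent two-way model
#' `y[i, j] = mu + subject[i] + session[j, i] + error[i, j]` with the
#' variance triple implied by `icc`, `total_var` and `session_share` — the
#' feature-level view of the generator, used for estimator calibration
#' (parameter recovery, confidence-interval coverage, power simulation)
#' without synthesizing waveforms.
#'
#' @inheritParams variance_components_for_icc
#' @param n,k Numbers of subjects and visits.
#' @param icc True intraclass correlation.
#' @param mu Grand mean.
#' @param total_var Total variance of one measurement.
#' @return An `n x k` numeric matrix.
#' @export
simulate_paired_measurements <- function(n, k, icc, total_var = 1,
                                         session_share = 0.3, mu = 0) {
  n <- assert_count(n, "n", lower = 2)
  k <- assert_count(k, "k", lower = 2)
  vc <- variance_components_for_icc(icc, total_var, session_share)
  subj <- rnorm(n, 0, sqrt(vc[["subject"]]))
  sess <- rnorm(k, 0, sqrt(vc[["session"]]))
  err <- matrix(rnorm(n * k, 0, sqrt(vc[["error"]])), n, k)
  mu + outer(subj, sess, "+") + err
}
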