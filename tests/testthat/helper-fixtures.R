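# Shared fixtures: everything is generated in code at test time.

# Small, fast simulation settings used across tests: 8 channels, 60 s at
# 250 Hz keeps a full preprocess + Welch cycle under a second per recording.
quick_spec <- function(...) {
  args <- utils::modifyList(
    list(
      n_subjects = 2, sessions_per_subject = 2,
      fs = 250, duration = 60, n_channels = 8, seed = 42
    ),
    list(...)
  )
  do.call(simulation_spec, args)
}

sine_recording <- function(freq, fs = 250, duration = 30, n_ch = 1,
                           amplitude = 1, noise_sd = 0) {
  t <- (seq_len(fs * duration) - 1) / fs
  data <- matrix(rep(amplitude * sin(2 * pi * freq * t), each = n_ch),
    nrow = n_ch, byrow = FALSE
  )
  if (noise_sd > 0) data <- data + matrix(rnorm(length(data), 0, noise_sd), nrow = n_ch)
  eeg_recording(data, fs)
}

# Independent ANOVA oracle: explicit cell-loop sums of squares, then the
# agreement formula from the raw SS (a separate arithmetic path from the
# package's row/column-mean implementation).
oracle_icc_a1 <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  gm <- sum(x) / (n * k)
  ss_total <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) ss_total <- ss_total + (x[i, j] - gm)^2
  ss_subj <- 0
  for (i in seq_len(n)) ss_subj <- ss_subj + k * (sum(x[i, ]) / k - gm)^2
  ss_visit <- 0
  for (j in seq_len(k)) ss_visit <- ss_visit + n * (sum(x[, j]) / n - gm)^2
  bms <- ss_subj / (n - 1)
  rms <- ss_visit / (k - 1)
  ems <- (ss_total - ss_subj - ss_visit) / ((n - 1) * (k - 1))
  (bms - ems) / (bms + (k - 1) * ems + (k / n) * (rms - ems))
}

# Feature table with a known latent ICC per feature, bypassing waveform
# synthesis (used where only estimator behaviour is under test). Means and
# variances keep rbp values inside [0, 1] and ipf inside [5, 14] without any
# transform, so the latent ICC carries through exactly.
latent_feature_table <- function(n, icc_by_feature, session_ids = c("V1", "V2")) {
  rows <- list()
  for (fn in names(icc_by_feature)) {
    mu <- if (fn == "ipf") 10 else 0.3
    total_var <- if (fn == "ipf") 0.04 else 0.002
    m <- simulate_paired_measurements(n, length(session_ids), icc_by_feature[[fn]],
      total_var = total_var, mu = mu
    )
    m <- pmin(pmax(m, if (fn == "ipf") 5 else 0), if (fn == "ipf") 14 else 1)
    for (j in seq_along(session_ids)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = sprintf("S%03d", seq_len(n)),
        session_id = session_ids[j],
        feature_name = fn,
        value = m[, j]
      )
    }
  }
  dplyr::bind_rows(rows)
}
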