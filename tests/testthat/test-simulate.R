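test_that("variance components reproduce the ICC definition", {
  expect_equal(
    variance_components_for_icc(0.0, 1.0, 0.5),
    c(subject = 0, session = 0.5, error = 0.5)
  )
  expect_equal(
    variance_components_for_icc(1.0, 2.0, 0.7),
    c(subject = 2, session = 0, error = 0)
  )
  expect_equal(
    variance_components_for_icc(0.8, 1.0, 0.25),
    c(subject = 0.8, session = 0.05, error = 0.15)
  )
  # components always sum to the total and reproduce the target ratio
  set.seed(5)
  for (i in 1:25) {
    icc <- runif(1)
    tot <- runif(1, 0.1, 5)
    sh <- runif(1)
    vc <- variance_components_for_icc(icc, tot, sh)
    expect_equal(sum(vc), tot)
    expect_equal(vc[["subject"]] / tot, icc)
    expect_true(all(vc >= 0))
  }
})

test_that("latent profiles are deterministic and respect degenerate variances", {
  spec0 <- quick_spec(
    band_log_amp_var = 0, alpha_peak_freq_sd = 0,
    icc_targets = c(
      rbp_delta = 1, rbp_theta = 1, rbp_alpha = 1,
      rbp_beta = 1, rbp_gamma = 1, ipf = 1
    ),
    n_subjects = 3
  )
  tr0 <- sample_subject_profiles(spec0)
  # no variance anywhere: all subjects and sessions identical
  expect_true(all(apply(tr0$log_amp, 3, function(m) max(m) - min(m)) == 0))
  expect_equal(max(tr0$peak_freq) - min(tr0$peak_freq), 0)

  spec <- quick_spec(n_subjects = 4)
  expect_identical(sample_subject_profiles(spec), sample_subject_profiles(spec))

  # counter-based streams: enlarging the study leaves old subjects untouched
  tr4 <- sample_subject_profiles(quick_spec(n_subjects = 4))
  tr6 <- sample_subject_profiles(quick_spec(n_subjects = 6))
  expect_identical(tr4$log_amp, tr6$log_amp[1:4, , , drop = FALSE])
  expect_identical(tr4$peak_freq, tr6$peak_freq[1:4, , drop = FALSE])
})

test_that("latent variance ratio converges to the target ICC at large n", {
  spec <- quick_spec(
    n_subjects = 2000,
    icc_targets = c(
      rbp_delta = 0.8, rbp_theta = 0.8, rbp_alpha = 0.8,
      rbp_beta = 0.8, rbp_gamma = 0.8, ipf = 0.8
    )
  )
  tr <- sample_subject_profiles(spec)
  est <- icc_a1(tr$log_amp[, , "alpha"])
  expect_gt(est, 0.77)
  expect_lt(est, 0.83)
})

test_that("synthesized sessions have the constructed spectral content", {
  # near-pure 10 Hz oscillation: peak lands on the 10 Hz Welch bin
  spec_tone <- quick_spec(
    n_subjects = 1,
    alpha_peak_freq_mean = 10, alpha_peak_freq_sd = 0,
    band_log_amp_mean = log(c(delta = 1, theta = 1, alpha = 1, beta = 1, gamma = 1) * 1e-4),
    background_rms = 1e-4, alpha_osc_gain = 1e4,
    icc_targets = c(
      rbp_delta = 1, rbp_theta = 1, rbp_alpha = 1,
      rbp_beta = 1, rbp_gamma = 1, ipf = 1
    )
  )
  tr <- sample_subject_profiles(spec_tone)
  rec <- synthesize_session(tr, 1, 1, spec_tone)
  expect_equal(ncol(rec$data), 250 * 60) # duration bookkeeping
  ps <- welch_psd(segment_epochs(rec, 2))
  expect_equal(ps$freqs[which.max(ps$absolute[1, ])], 10)

  # line-noise artifact: 60 Hz bin at least 20 dB above its neighbours
  spec_line <- quick_spec(n_subjects = 1, line_noise_60hz = TRUE)
  tr2 <- sample_subject_profiles(spec_line)
  rec2 <- synthesize_session(tr2, 1, 1, spec_line)
  ps2 <- welch_psd(segment_epochs(rec2, 2))
  i60 <- which(ps2$freqs == 60)
  p60 <- ps2$absolute[1, i60]
  nbr <- max(ps2$absolute[1, c(i60 - 3, i60 + 3)])
  expect_gt(10 * log10(p60 / nbr), 20)

  # flat bad channels are injected where requested
  spec_bad <- quick_spec(n_subjects = 1, n_bad_channels = 1)
  tr3 <- sample_subject_profiles(spec_bad)
  rec3 <- synthesize_session(tr3, 1, 1, spec_bad)
  expect_equal(sum(apply(rec3$data, 1, var) == 0), 1L)
})

test_that("aperiodic background follows the configured 1/f slope", {
  spec <- quick_spec(
    n_subjects = 1, duration = 120,
    aperiodic_exponent_mean = 1.5, aperiodic_exponent_sd = 0,
    band_log_amp_mean = log(c(delta = 1, theta = 1, alpha = 1, beta = 1, gamma = 1) * 1e-6),
    alpha_osc_gain = 0, background_rms = 5
  )
  tr <- sample_subject_profiles(spec)
  rec <- synthesize_session(tr, 1, 1, spec)
  ps <- welch_psd(segment_epochs(rec, 2))
  sel <- ps$freqs >= 2 & ps$freqs <= 40
  mean_psd <- colMeans(ps$absolute)[sel]
  slope <- coef(lm(log(mean_psd) ~ log(ps$freqs[sel])))[2]
  expect_equal(unname(slope), -1.5, tolerance = 0.2 / 1.5)
})

test_that("generate_dataset writes a reproducible study to disk", {
  spec <- quick_spec(n_subjects = 3, duration = 10)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  ds <- generate_dataset(spec, out_dir = d1)
  expect_length(ds$recordings, 6L)
  expect_equal(nrow(ds$sessions), 6L)
  expect_setequal(unique(ds$sessions$interval_label), "same_day")
  generate_dataset(spec, out_dir = d2)
  f1 <- list.files(d1, pattern = "edf$")
  expect_length(f1, 6L)
  for (f in f1) {
    expect_identical(
      unname(tools::md5sum(file.path(d1, f))),
      unname(tools::md5sum(file.path(d2, f)))
    ) # byte-identical under the same seed
  }
  truth_icc <- readr::read_csv(file.path(d1, "ground_truth_icc.csv"),
    show_col_types = FALSE
  )
  expect_equal(nrow(truth_icc), 6L)

  # longitudinal design labels: baseline then week intervals
  spec_l <- quick_spec(
    n_subjects = 2, sessions_per_subject = 4, duration = 10,
    interval_design = "longitudinal"
  )
  ds_l <- generate_dataset(spec_l)
  expect_setequal(unique(ds_l$sessions$interval_label), c("baseline", "2wk", "4wk", "6wk"))
})
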