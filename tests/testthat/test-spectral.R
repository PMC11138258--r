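# Hand-built power_spectrum objects let band logic be tested against a
# brute-force oracle without running Welch.
make_ps <- function(absolute, fs = 250) {
  nfreq <- ncol(absolute)
  structure(
    list(
      freqs = (seq_len(nfreq) - 1) * 0.5, absolute = absolute,
      relative = NULL, rel_freqs = NULL,
      undefined = rep(FALSE, nrow(absolute)),
      fs = fs, n_segments = 1L,
      channel_labels = paste0("E", seq_len(nrow(absolute)))
    ),
    class = "power_spectrum"
  )
}

test_that("Welch PSD integrates to the signal variance and localizes tones", {
  set.seed(21)
  fs <- 250
  rec <- eeg_recording(matrix(rnorm(fs * 120), 1), fs)
  ps <- welch_psd(segment_epochs(rec, 2))
  df <- ps$freqs[2] - ps$freqs[1]
  expect_equal(df, 0.5)
  expect_equal(sum(ps$absolute[1, ]) * df, var(rec$data[1, ]), tolerance = 0.05)

  t <- (0:(fs * 60 - 1)) / fs
  ps_tone <- welch_psd(segment_epochs(eeg_recording(matrix(sin(2 * pi * 10 * t), 1), fs), 2))
  expect_equal(ps_tone$freqs[which.max(ps_tone$absolute[1, ])], 10)

  # off-grid tone: leakage splits between the flanking bins
  ps_off <- welch_psd(segment_epochs(eeg_recording(matrix(sin(2 * pi * 10.25 * t), 1), fs), 2))
  expect_true(ps_off$freqs[which.max(ps_off$absolute[1, ])] %in% c(10, 10.5))
})

test_that("Welch segments never span a rejection gap", {
  fs <- 100
  # constant-per-epoch signal: any segment crossing a gap would mix values
  rec <- eeg_recording(matrix(rep(1:10, each = 2 * fs), 1), fs)
  es <- segment_epochs(rec, 2)
  es$kept_mask <- rep(c(TRUE, FALSE), 5)
  ps <- welch_psd(es)
  # 5 isolated kept epochs -> exactly one 2 s segment each
  expect_equal(ps$n_segments, 5L)
})

test_that("relative power normalizes to one and is scale invariant", {
  set.seed(3)
  abs_spec <- matrix(rexp(4 * 251), 4, 251) # 0..125 Hz at 0.5 Hz
  ps <- relative_power(make_ps(abs_spec))
  expect_true(all(abs(rowSums(ps$relative) - 1) < 1e-9))
  ps_scaled <- relative_power(make_ps(abs_spec * 1000))
  expect_equal(ps_scaled$relative, ps$relative, tolerance = 1e-12)

  # spectrum confined to the alpha band
  conc <- matrix(0, 1, 251)
  conc[1, make_ps(conc)$freqs >= 8 & make_ps(conc)$freqs <= 12.5] <- 5
  bp <- band_powers(relative_power(make_ps(conc)))
  expect_equal(unname(bp["alpha", 1]), sum(bp[, 1]))
  expect_true(all(bp[c("delta", "theta", "beta", "gamma"), 1] == 0))

  # flat channel flagged undefined with a warning
  abs_flat <- abs_spec
  abs_flat[2, ] <- 0
  expect_warning(psf <- relative_power(make_ps(abs_flat)), "undefined")
  expect_true(psf$undefined[2])
})

test_that("band powers match a brute-force oracle over the documented bins", {
  set.seed(31)
  abs_spec <- matrix(rexp(3 * 251), 3, 251)
  ps <- relative_power(make_ps(abs_spec))
  bp <- band_powers(ps)

  edges <- list(
    delta = c(2, 3.5), theta = c(4, 7.5), alpha = c(8, 12.5),
    beta = c(13, 30), gamma = c(30, 80)
  )
  for (ch in 1:3) {
    assigned <- rep(FALSE, length(ps$rel_freqs))
    for (b in names(edges)) {
      idx <- which(!assigned & ps$rel_freqs >= edges[[b]][1] & ps$rel_freqs <= edges[[b]][2])
      assigned[idx] <- TRUE
      if (b == "gamma") idx <- setdiff(idx, which(ps$rel_freqs >= 55 & ps$rel_freqs <= 65))
      expect_equal(unname(bp[b, ch]), mean(ps$relative[ch, idx]), tolerance = 1e-12)
    }
  }
  # the shared 30 Hz bin belongs to beta, not gamma
  conc30 <- matrix(1e-12, 1, 251)
  conc30[1, 61] <- 1 # 30.0 Hz bin
  bp30 <- band_powers(relative_power(make_ps(conc30)))
  expect_gt(bp30["beta", 1], bp30["gamma", 1])

  # mains-stopband bins cannot inflate gamma
  huge <- abs_spec
  sb <- which(ps$rel_freqs >= 55 & ps$rel_freqs <= 65)
  ps_h <- relative_power(make_ps(huge))
  ps_h$relative[, sb + 0] <- 99 # tamper only the stopband relative bins
  bp_h <- band_powers(ps_h)
  ps_r <- relative_power(make_ps(huge))
  expect_equal(bp_h["gamma", ], band_powers(ps_r)["gamma", ], tolerance = 1e-12)

  # conservation: sum over bands of rbp * bin-count equals banded mass
  assign <- eegretest:::band_bin_assignment(ps$rel_freqs)
  counts <- table(assign)[rownames(bp)]
  mass <- sum(bp[, 1] * as.numeric(counts))
  expect_equal(mass, sum(ps$relative[1, !is.na(assign)]), tolerance = 1e-9)
})

test_that("individual peak frequency follows the argmax and tie rules", {
  base <- matrix(1e-3, 1, 251)
  ps_f <- make_ps(base)
  # dominant 10 Hz peak over a decaying background
  spec <- base
  spec[1, ] <- 1 / (ps_f$freqs + 1)
  spec[1, ps_f$freqs == 10] <- 2
  expect_equal(unname(individual_peak_frequency(relative_power(make_ps(spec)))[1]), 10)

  # strictly decreasing spectrum: window edge at 5 Hz
  mono <- base
  mono[1, ] <- exp(-0.3 * ps_f$freqs)
  ipf_mono <- individual_peak_frequency(relative_power(make_ps(mono)))
  expect_equal(unname(ipf_mono[1]), 5)
  expect_gte(attr(ipf_mono, "n_edge"), 1L)

  # exact tie at 9 and 11 Hz resolves to the lower frequency
  tie <- base
  tie[1, ps_f$freqs %in% c(9, 11)] <- 7
  expect_equal(unname(individual_peak_frequency(relative_power(make_ps(tie)))[1]), 9)
})

test_that("montage averaging uses analysis channels and drops undefined ones", {
  mont <- synthetic_montage(8, n_excluded = 2)
  vals <- setNames(as.numeric(1:8), mont$label)
  keep <- !mont$excluded
  expect_equal(montage_average(vals, mont), mean(vals[keep]))

  vals[which(keep)[1]] <- NA
  expect_warning(avg <- montage_average(vals, mont), "undefined")
  expect_equal(avg, mean(vals[keep], na.rm = TRUE))

  all_na <- setNames(rep(NA_real_, 8), mont$label)
  expect_error(
    suppressWarnings(montage_average(all_na, mont)),
    class = "eegretest_data_quality_error"
  )
})

test_that("features are invariant to signal scaling and pin the alpha IPF", {
  for (f_alpha in c(8.5, 10, 12)) {
    spec <- quick_spec(
      n_subjects = 1, duration = 30,
      alpha_peak_freq_mean = f_alpha, alpha_peak_freq_sd = 0,
      alpha_osc_gain = 6
    )
    tr <- sample_subject_profiles(spec)
    mont <- synthetic_montage(8)
    rec <- synthesize_session(tr, 1, 1, spec, mont)
    es <- segment_epochs(apply_filters(rec), 2)
    feats <- compute_features(es, mont)
    expect_equal(feats$value[feats$feature_name == "ipf"], f_alpha)

    rec3 <- rec
    rec3$data <- rec3$data * 3
    feats3 <- compute_features(segment_epochs(apply_filters(rec3), 2), mont)
    expect_equal(feats3$value, feats$value, tolerance = 1e-9)
  }
})
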