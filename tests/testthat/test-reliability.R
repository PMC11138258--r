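test_that("session pairing is listwise-complete per interval", {
  feats <- latent_feature_table(3, c(rbp_alpha = 0.9, ipf = 0.9))
  sess <- session_table(
    rep(sprintf("S%03d", 1:3), each = 2),
    rep(c("V1", "V2"), 3),
    as.POSIXct("2024-01-01 09:00", tz = "UTC") + rep(c(0, 5 * 3600), 3),
    "same_day"
  )
  pm <- pair_sessions(feats, sess, "same_day")
  expect_equal(dim(pm$rbp_alpha$values), c(3L, 2L))

  # drop subject 3's second visit: that subject vanishes from the pairing
  sess2 <- sess[-6, ]
  feats2 <- dplyr::anti_join(feats,
    tibble::tibble(subject_id = "S003", session_id = "V2"),
    by = c("subject_id", "session_id")
  )
  pm2 <- pair_sessions(feats2, sess2, "same_day")
  expect_equal(dim(pm2$rbp_alpha$values), c(2L, 2L))
  expect_setequal(pm2$rbp_alpha$subject_ids, c("S001", "S002"))

  expect_error(pair_sessions(feats, sess, "2wk"),
    class = "eegretest_insufficient_data_error"
  )

  # week intervals pair baseline with the labelled follow-up
  sess_l <- session_table(
    rep(c("S001", "S002"), each = 2),
    rep(c("V1", "V2"), 2),
    as.POSIXct("2024-01-01 09:00", tz = "UTC") + rep(c(0, 14 * 86400), 2),
    rep(c("baseline", "2wk"), 2)
  )
  pm_l <- pair_sessions(latent_feature_table(2, c(ipf = 0.9)), sess_l, "2wk")
  expect_equal(dim(pm_l$ipf$values), c(2L, 2L))
})

test_that("two-way mean squares match hand-computed ANOVA tables", {
  ms <- anova_mean_squares(matrix(c(1, 1, 2, 2, 3, 3), 3, 2, byrow = TRUE))
  expect_equal(ms$bms, 2)
  expect_equal(ms$rms, 0)
  expect_equal(ms$ems, 0)

  ms2 <- anova_mean_squares(matrix(c(1, 2, 1, 2, 1, 2), 3, 2, byrow = TRUE))
  expect_equal(ms2$bms, 0)
  expect_equal(ms2$rms, 1.5)
  expect_equal(ms2$ems, 0)

  # decomposition identity and agreement with stats::aov on random matrices
  set.seed(11)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    k <- sample(2:4, 1)
    x <- matrix(rnorm(n * k), n, k)
    m <- anova_mean_squares(x)
    tot <- sum((x - mean(x))^2)
    expect_equal(
      (n - 1) * m$bms + (k - 1) * m$rms + (n - 1) * (k - 1) * m$ems,
      tot,
      tolerance = 1e-10
    )
    df <- data.frame(
      y = as.vector(x),
      subj = factor(rep(seq_len(n), k)),
      visit = factor(rep(seq_len(k), each = n))
    )
    aovtab <- summary(stats::aov(y ~ subj + visit, data = df))[[1]]
    expect_equal(m$bms, aovtab["subj", "Mean Sq"], tolerance = 1e-10)
    expect_equal(m$rms, aovtab["visit", "Mean Sq"], tolerance = 1e-10)
    expect_equal(m$ems, aovtab["Residuals", "Mean Sq"], tolerance = 1e-10)
  }
})

test_that("ICC(A,1) matches the independent oracle and known cases", {
  expect_equal(icc_a1(matrix(c(1, 1, 2, 2, 3, 3), 3, 2, byrow = TRUE)), 1)
  # pure visit shift with no subject variance carries no reliability
  expect_lte(icc_a1(matrix(c(1, 2, 1, 2, 1, 2), 3, 2, byrow = TRUE)), 0)

  set.seed(13)
  for (i in 1:50) {
    x <- matrix(rnorm(10 * 2, sd = runif(1, 0.5, 3)), 10, 2)
    expect_equal(icc_a1(x), oracle_icc_a1(x), tolerance = 1e-10)
  }

  # large-sample agreement with an REML variance-components oracle
  skip_if_not_installed("lme4")
  set.seed(17)
  x <- simulate_paired_measurements(500, 2, icc = 0.8)
  df <- data.frame(
    y = as.vector(x),
    subj = factor(rep(1:500, 2)),
    visit = factor(rep(1:2, each = 500))
  )
  fit <- lme4::lmer(y ~ 1 + (1 | subj) + (1 | visit), data = df)
  vc <- as.data.frame(lme4::VarCorr(fit))
  v <- setNames(vc$vcov, vc$grp)
  reml_icc <- v[["subj"]] / (v[["subj"]] + v[["visit"]] + v[["Residual"]])
  expect_equal(icc_a1(x), unname(reml_icc), tolerance = 0.05)
})

test_that("the printed-formula variant differs as documented", {
  set.seed(19)
  x <- matrix(rnorm(20), 10, 2)
  ms <- anova_mean_squares(x)
  mcg <- icc_a1(ms)
  prn <- icc_a1(ms, variant = "printed")
  k <- 2
  expect_equal(
    prn,
    (ms$bms - ms$ems) / (ms$bms + (k + 1) * ms$ems + (k / ms$n) * (ms$rms - ms$ems))
  )
  expect_true(abs(prn) <= abs(mcg)) # larger denominator shrinks the estimate
})

test_that("ICC is invariant to location/scale and sensitive to visit offsets", {
  set.seed(23)
  x <- simulate_paired_measurements(25, 2, icc = 0.7)
  base <- icc_a1(x)
  expect_equal(icc_a1(x + 100), base, tolerance = 1e-10)
  expect_equal(icc_a1(x * 7), base, tolerance = 1e-10)
  shifted <- x
  shifted[, 2] <- shifted[, 2] + 2 * sd(x)
  expect_lt(icc_a1(shifted), base) # absolute agreement penalizes offsets
})

test_that("confidence intervals behave across agreement regimes", {
  ci_perf <- icc_confidence_interval(anova_mean_squares(matrix(c(1, 1, 2, 2, 3, 3), 3, 2, byrow = TRUE)))
  expect_gt(ci_perf[["ci_low"]], 0.99)

  ci_deg <- icc_confidence_interval(anova_mean_squares(matrix(5, 3, 2)))
  expect_true(isTRUE(attr(ci_deg, "degenerate")))
  expect_equal(as.numeric(ci_deg), c(-1, 1))

  # CI width shrinks with n on matched simulations
  set.seed(29)
  width <- function(n) {
    mean(replicate(40, {
      x <- simulate_paired_measurements(n, 2, icc = 0.85)
      ci <- icc_confidence_interval(anova_mean_squares(x))
      ci[["ci_high"]] - ci[["ci_low"]]
    }))
  }
  expect_gt(width(10), width(30))

  fit <- icc_fit(simulate_paired_measurements(30, 2, icc = 0.85))
  expect_lte(fit$ci_low, fit$estimate)
  expect_gte(fit$ci_high, fit$estimate)
})

test_that("reliability classes use left-closed conventional bands", {
  expect_equal(classify_reliability(0.959), "excellent")
  expect_equal(classify_reliability(0.5), "moderate")
  expect_equal(classify_reliability(0.49), "poor")
  expect_equal(
    classify_reliability(c(-0.3, 0.75, 0.9, 1)),
    c("poor", "good", "excellent", "excellent")
  )
  expect_error(classify_reliability(1.2), class = "eegretest_validation_error")
})

test_that("reliability_table assembles the features-by-intervals grid", {
  set.seed(31)
  n <- 12
  iccs <- c(
    rbp_delta = 0.8, rbp_theta = 0.8, rbp_alpha = 0.9,
    rbp_beta = 0.8, rbp_gamma = 0.8, ipf = 0.85
  )
  sess <- NULL
  feats <- NULL
  for (iv in c("2wk", "4wk", "6wk")) {
    # one baseline + follow-up block per interval, separate pseudo-subjects
    ids <- sprintf("%s_S%02d", iv, seq_len(n))
    f <- latent_feature_table(n, iccs)
    f$subject_id <- rep(rep(ids, 2), length(iccs))[seq_len(nrow(f))]
    s <- session_table(
      rep(ids, each = 2), rep(c("V1", "V2"), n),
      as.POSIXct("2024-01-01", tz = "UTC") + seq_len(2 * n) * 3600,
      rep(c("baseline", iv), n)
    )
    sess <- dplyr::bind_rows(sess, s)
    feats <- dplyr::bind_rows(feats, f)
  }
  sd_ids <- sprintf("sd_S%02d", seq_len(n))
  f_sd <- latent_feature_table(n, iccs)
  f_sd$subject_id <- rep(rep(sd_ids, 2), length(iccs))[seq_len(nrow(f_sd))]
  s_sd <- session_table(
    rep(sd_ids, each = 2), rep(c("V1", "V2"), n),
    as.POSIXct("2024-06-01", tz = "UTC") + seq_len(2 * n) * 3600,
    "same_day"
  )
  tbl <- reliability_table(
    dplyr::bind_rows(feats, f_sd),
    dplyr::bind_rows(sess, s_sd)
  )
  expect_s3_class(tbl, "reliability_table")
  expect_equal(nrow(tbl), 24L) # 6 features x 4 intervals
  expect_true(all(!is.na(tbl$estimate)))
  expect_true(all(tbl$n == n))

  p <- withr::local_tempfile(fileext = ".csv")
  write_reliability_table(tbl, p)
  wide <- readr::read_csv(p, show_col_types = FALSE)
  expect_equal(nrow(wide), 6L)
  expect_true("same_day_estimate" %in% names(wide))

  expect_error(
    reliability_table(
      tibble::tibble(
        subject_id = character(), session_id = character(),
        feature_name = character(), value = numeric()
      ),
      s_sd
    ),
    class = "eegretest_insufficient_data_error"
  )
})

test_that("tidy and glance return one-row summaries", {
  set.seed(37)
  fit <- icc_fit(simulate_paired_measurements(20, 2, icc = 0.8))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1L)
  expect_named(td, c(
    "feature_name", "interval_label", "estimate", "ci_low",
    "ci_high", "n", "k", "reliability_class"
  ))
  gl <- glance(fit)
  expect_true(all(c("bms", "rms", "ems", "wms") %in% names(gl)))
})
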