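#' Pair sessions into an n-subjects x k-visits matrix per feature
#'
#' Joins the feature table with the session table and assembles, for one
#' inter-session interval, the listwise-complete measurement matrix of each
#' feature. For `"same_day"` the pair is the first `k` sessions carrying
#' that label (ordered by session time); for the week intervals the pair is
#' the subject's `baseline` session plus the session carrying the interval
#' label. Subjects lacking either visit are dropped.
#'
#' @param features A feature table (see [eeg_tables]).
#' @param sessions A session table.
#' @param interval_label One of `"same_day"`, `"2wk"`, `"4wk"`, `"6wk"`.
#' @param k Number of visits per subject in the pairing (default 2).
#' @return A named list (one element per feature) of `paired_measurements`
#'   objects: `values` (n x k matrix), `feature_name`, `interval_label`,
#'   `subject_ids`.
#' @export
pair_sessions <- function(features, sessions, interval_label, k = 2) {
  validate_feature_table(features)
  validate_session_table(sessions)
  k <- assert_count(k, "k", lower = 2)
  if (!interval_label %in% setdiff(interval_levels(), "baseline")) {
    stop_validation(paste0("`interval_label` must be one of: ",
      paste(setdiff(interval_levels(), "baseline"), collapse = ", ")))
  }

  wanted <- if (interval_label == "same_day") {
    ses <- dplyr::filter(sessions, .data$interval_label == "same_day")
    ses <- dplyr::arrange(ses, .data$subject_id, .data$session_datetime)
    ses <- dplyr::group_by(ses, .data$subject_id)
    ses <- dplyr::slice_head(ses, n = k)
    dplyr::mutate(dplyr::ungroup(ses), visit = NA_integer_)
  } else {
    ses <- dplyr::filter(sessions, .data$interval_label %in% c("baseline", !!interval_label))
    ses <- dplyr::arrange(ses, .data$subject_id, .data$session_datetime)
    dplyr::mutate(ses, visit = NA_integer_)
  }
  if (nrow(wanted) == 0) {
    stop_insufficient_data(paste0("No sessions labelled for interval '", interval_label, "'."))
  }
  wanted <- dplyr::group_by(wanted, .data$subject_id)
  wanted <- dplyr::mutate(wanted, visit = dplyr::row_number())
  wanted <- dplyr::ungroup(wanted)
  # complete subjects only
  counts <- dplyr::count(wanted, .data$subject_id)
  complete <- counts$subject_id[counts$n == k]
  wanted <- dplyr::filter(wanted, .data$subject_id %in% complete, .data$visit <= k)
  if (length(complete) < 2) {
    stop_insufficient_data(sprintf(
      "Interval '%s': %d complete subject(s); at least 2 required.",
      interval_label, length(complete)
    ))
  }

  joined <- dplyr::inner_join(wanted, features, by = c("subject_id", "session_id"))
  feats <- intersect(feature_levels(), unique(joined$feature_name))
  if (!length(feats)) stop_insufficient_data("No feature values for the paired sessions.")

  out <- lapply(setNames(feats, feats), function(fn) {
    sub <- dplyr::filter(joined, .data$feature_name == fn)
    wide <- tidyr::pivot_wider(sub[, c("subject_id", "visit", "value")],
      names_from = "visit", values_from = "value"
    )
    wide <- wide[complete.cases(wide), , drop = FALSE]
    if (nrow(wide) < 2) {
      stop_insufficient_data(sprintf(
        "Feature %s at interval '%s': fewer than 2 complete subjects.", fn, interval_label
      ))
    }
    m <- as.matrix(wide[, as.character(seq_len(k)), drop = FALSE])
    rownames(m) <- wide$subject_id
    structure(
      list(
        values = unname(m), feature_name = fn, interval_label = interval_label,
        subject_ids = wide$subject_id
      ),
      class = "paired_measurements"
    )
  })
  out
}

#' Two-way ANOVA mean squares of a subjects x visits matrix
#'
#' The replication-free two-way decomposition underlying ICC(A,1): BMS
#' (between subjects, n-1 df), RMS (between visits, k-1 df), EMS (residual,
#' (n-1)(k-1) df) and WMS (within subjects, n(k-1) df). The identity
#' `(n-1)BMS + (k-1)RMS + (n-1)(k-1)EMS = total SS` holds exactly.
#'
#' @param x Numeric n x k matrix (or a `paired_measurements`).
#' @return A `mean_squares` list with `bms`, `rms`, `ems`, `wms`, the df
#'   terms, `n`, `k` and a `degenerate` flag (zero total variance).
#' @export
anova_mean_squares <- function(x) {
  if (inherits(x, "paired_measurements")) x <- x$values
  x <- as.matrix(x)
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2 || k < 2) stop_validation("Need n >= 2 subjects and k >= 2 visits.")
  if (any(!is.finite(x))) stop_validation("Paired measurements must be complete and finite.")
  gm <- mean(x)
  ss_total <- sum((x - gm)^2)
  ss_subj <- k * sum((rowMeans(x) - gm)^2)
  ss_visit <- n * sum((colMeans(x) - gm)^2)
  ss_err <- ss_total - ss_subj - ss_visit
  ss_err <- max(ss_err, 0)
  structure(
    list(
      bms = ss_subj / (n - 1),
      rms = ss_visit / (k - 1),
      ems = ss_err / ((n - 1) * (k - 1)),
      wms = (ss_visit + ss_err) / (n * (k - 1)),
      df_subject = n - 1, df_visit = k - 1,
      df_error = (n - 1) * (k - 1), df_within = n * (k - 1),
      n = n, k = k,
      degenerate = ss_total == 0
    ),
    class = "mean_squares"
  )
}

#' ICC(A,1): two-way random effects, absolute agreement, single measurement
#'
#' The moment estimator
#' `(BMS - EMS) / (BMS + (k - 1) EMS + (k / n) (RMS - EMS))`
#' (McGraw-Wong form). `variant = "printed"` substitutes `(k + 1) EMS` in
#' the denominator — a published typographical variant retained for audit
#' only; it does not correspond to the A,1 model.
#'
#' @param ms A `mean_squares` object (or an n x k matrix).
#' @param n,k Numbers of subjects and visits (taken from `ms` if absent).
#' @param variant `"mcgraw"` (default) or `"printed"`.
#' @return The ICC estimate (may be negative; `NaN` when the denominator is
#'   zero).
#' @export
icc_a1 <- function(ms, n = NULL, k = NULL, variant = c("mcgraw", "printed")) {
  variant <- match.arg(variant)
  if (is.matrix(ms) || is.data.frame(ms)) ms <- anova_mean_squares(ms)
  if (inherits(ms, "paired_measurements")) ms <- anova_mean_squares(ms)
  n <- n %||% ms$n
  k <- k %||% ms$k
  coef_ems <- if (variant == "mcgraw") k - 1 else k + 1
  den <- ms$bms + coef_ems * ms$ems + (k / n) * (ms$rms - ms$ems)
  if (den == 0) {
    return(NaN)
  }
  (ms$bms - ms$ems) / den
}

#' McGraw-Wong 95% confidence interval for ICC(A,1)
#'
#' F-based approximate interval for the two-way random-effects,
#' absolute-agreement, single-measure ICC, with Satterthwaite denominator
#' degrees of freedom. Degenerate mean squares give the uninformative
#' interval \[-1, 1\] with a flag.
#'
#' @inheritParams icc_a1
#' @param level Confidence level (default 0.95).
#' @return Named vector `c(ci_low=, ci_high=)` (attribute `degenerate` when
#'   flagged).
#' @export
icc_confidence_interval <- function(ms, n = NULL, k = NULL, level = 0.95) {
  if (is.matrix(ms) || is.data.frame(ms)) ms <- anova_mean_squares(ms)
  if (inherits(ms, "paired_measurements")) ms <- anova_mean_squares(ms)
  n <- n %||% ms$n
  k <- k %||% ms$k
  assert_scalar_number(level, "level", 0.5, 1 - 1e-12)
  if (ms$degenerate || (ms$ems == 0 && ms$bms == 0)) {
    return(structure(c(ci_low = -1, ci_high = 1), degenerate = TRUE))
  }
  r <- icc_a1(ms, n, k)
  if (!is.finite(r)) {
    return(structure(c(ci_low = -1, ci_high = 1), degenerate = TRUE))
  }
  alpha <- 1 - level
  r_ <- min(r, 1 - 1e-10) # keep the Satterthwaite terms finite at r = 1
  a <- (k * r_) / (n * (1 - r_))
  b <- 1 + (k * r_ * (n - 1)) / (n * (1 - r_))
  v_num <- (a * ms$rms + b * ms$ems)^2
  v_den <- (a * ms$rms)^2 / (k - 1) + (b * ms$ems)^2 / ((n - 1) * (k - 1))
  v <- v_num / v_den
  if (!is.finite(v) || v <= 0) v <- Inf
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lo <- n * (ms$bms - f_l * ms$ems) /
    (f_l * (k * ms$rms + (k * n - k - n) * ms$ems) + n * ms$bms)
  hi <- n * (f_u * ms$bms - ms$ems) /
    (k * ms$rms + (k * n - k - n) * ms$ems + n * f_u * ms$bms)
  c(ci_low = min(lo, hi), ci_high = max(lo, hi))
}

#' Classify an ICC estimate into reliability bands
#'
#' Conventional bands: poor < 0.5 <= moderate < 0.75 <= good < 0.9 <=
#' excellent <= 1 (left-closed at every threshold). Negative estimates are
#' poor.
#'
#' @param estimate ICC estimate(s), each <= 1.
#' @return Character vector of classes.
#' @export
classify_reliability <- function(estimate) {
  if (any(estimate > 1 + 1e-12, na.rm = TRUE)) {
    stop_validation("ICC estimates cannot exceed 1.")
  }
  lv <- c("poor", "moderate", "good", "excellent")
  idx <- cut(estimate, c(-Inf, 0.5, 0.75, 0.9, Inf), labels = FALSE, right = FALSE)
  ifelse(is.na(estimate), NA_character_, lv[idx])
}

#' Fit ICC(A,1) with confidence interval to paired measurements
#'
#' @param pm A `paired_measurements` object or an n x k matrix.
#' @param level Confidence level.
#' @param variant ICC formula variant, see [icc_a1()].
#' @return An `icc_fit` object with [tidy()] and [glance()] methods.
#' @export
icc_fit <- function(pm, level = 0.95, variant = "mcgraw") {
  vals <- if (inherits(pm, "paired_measurements")) pm$values else as.matrix(pm)
  ms <- anova_mean_squares(vals)
  est <- icc_a1(ms, variant = variant)
  ci <- icc_confidence_interval(ms, level = level)
  structure(
    list(
      estimate = est,
      ci_low = unname(ci["ci_low"]), ci_high = unname(ci["ci_high"]),
      level = level,
      n = ms$n, k = ms$k,
      mean_squares = ms,
      reliability_class = classify_reliability(min(est, 1)),
      feature_name = if (inherits(pm, "paired_measurements")) pm$feature_name else NA_character_,
      interval_label = if (inherits(pm, "paired_measurements")) pm$interval_label else NA_character_,
      variant = variant,
      degenerate = isTRUE(attr(ci, "degenerate"))
    ),
    class = "icc_fit"
  )
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf(
    "ICC(A,1) = %.3f [%.3f, %.3f] (%s), n = %d, k = %d%s\n",
    x$estimate, x$ci_low, x$ci_high, x$reliability_class, x$n, x$k,
    if (!is.na(x$feature_name)) paste0(" — ", x$feature_name, " @ ", x$interval_label) else ""
  ))
  invisible(x)
}

#' @rdname icc_fit
#' @param x An `icc_fit`.
#' @param ... Unused.
#' @method tidy icc_fit
#' @export
tidy.icc_fit <- function(x, ...) {
  tibble::tibble(
    feature_name = x$feature_name,
    interval_label = x$interval_label,
    estimate = x$estimate,
    ci_low = x$ci_low, ci_high = x$ci_high,
    n = x$n, k = x$k,
    reliability_class = x$reliability_class
  )
}

#' @rdname icc_fit
#' @method glance icc_fit
#' @export
glance.icc_fit <- function(x, ...) {
  ms <- x$mean_squares
  tibble::tibble(
    estimate = x$estimate, ci_low = x$ci_low, ci_high = x$ci_high,
    level = x$level, n = x$n, k = x$k,
    bms = ms$bms, rms = ms$rms, ems = ms$ems, wms = ms$wms,
    degenerate = ms$degenerate
  )
}

#' Reliability table: features x intervals
#'
#' Computes the ICC(A,1) estimate, confidence interval, per-interval n and
#' reliability class for every feature at every requested interval. Cells
#' with insufficient complete pairs are reported as missing with a reason.
#'
#' @param features A feature table.
#' @param sessions A session table.
#' @param intervals Intervals to evaluate (defaults to those present).
#' @param level Confidence level.
#' @param variant ICC formula variant (see [icc_a1()]).
#' @return A `reliability_table` tibble (long format: one row per feature x
#'   interval).
#' @export
reliability_table <- function(features, sessions,
                              intervals = NULL, level = 0.95,
                              variant = "mcgraw") {
  validate_feature_table(features)
  if (nrow(features) == 0) stop_insufficient_data("Feature table is empty.")
  present <- intersect(
    setdiff(interval_levels(), "baseline"),
    unique(sessions$interval_label)
  )
  intervals <- intervals %||% present
  if (!length(intervals)) stop_insufficient_data("No analyzable intervals in the session table.")

  rows <- list()
  for (iv in intervals) {
    pm_list <- tryCatch(pair_sessions(features, sessions, iv),
      eegretest_insufficient_data_error = function(e) e
    )
    for (fn in feature_levels()) {
      if (rlang::is_condition(pm_list) || is.null(pm_list[[fn]])) {
        reason <- if (rlang::is_condition(pm_list)) conditionMessage(pm_list) else "feature absent"
        rows[[length(rows) + 1L]] <- tibble::tibble(
          feature_name = fn, interval_label = iv,
          estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          n = NA_integer_, k = NA_integer_,
          reliability_class = NA_character_, reason = reason
        )
      } else {
        fit <- icc_fit(pm_list[[fn]], level = level, variant = variant)
        rows[[length(rows) + 1L]] <- dplyr::mutate(tidy(fit), reason = NA_character_)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out,
    feature_name = factor(.data$feature_name, levels = feature_levels()),
    interval_label = factor(.data$interval_label, levels = setdiff(interval_levels(), "baseline"))
  )
  out <- dplyr::arrange(out, .data$feature_name, .data$interval_label)
  class(out) <- c("reliability_table", class(out))
  out
}

#' Write a reliability table as a features x intervals CSV
#'
#' Wide layout mirroring a reliability summary table: one row per feature,
#' and per interval the estimate, CI bounds, n and class.
#'
#' @param tbl A `reliability_table`.
#' @param path Output CSV path.
#' @export
write_reliability_table <- function(tbl, path) {
  long <- dplyr::mutate(tibble::as_tibble(tbl),
    feature_name = as.character(.data$feature_name),
    interval_label = as.character(.data$interval_label)
  )
  wide <- tidyr::pivot_wider(
    long[, c(
      "feature_name", "interval_label", "estimate",
      "ci_low", "ci_high", "n", "reliability_class"
    )],
    names_from = "interval_label",
    values_from = c("estimate", "ci_low", "ci_high", "n", "reliability_class"),
    names_glue = "{interval_label}_{.value}"
  )
  readr::write_csv(wide, path)
  invisible(path)
}
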