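#' Session and feature tables
#'
#' Two long-format tibbles carry the tabular state of the pipeline. The
#' session table has one row per recording with columns `subject_id`,
#' `session_id`, `session_datetime` and `interval_label` (one of
#' `"same_day"`, `"2wk"`, `"4wk"`, `"6wk"`, `"baseline"`). The feature table
#' has one row per (subject, session, feature) with columns `subject_id`,
#' `session_id`, `feature_name` and `value`; features are the five relative
#' band powers (`rbp_delta` .. `rbp_gamma`, each in \[0, 1\]) and the
#' individual peak frequency `ipf` (in \[5, 14\] Hz).
#'
#' @name eeg_tables
NULL

interval_levels <- function() c("same_day", "2wk", "4wk", "6wk", "baseline")

feature_levels <- function() {
  c("rbp_delta", "rbp_theta", "rbp_alpha", "rbp_beta", "rbp_gamma", "ipf")
}

#' @rdname eeg_tables
#' @param subject_id,session_id,session_datetime,interval_label Column vectors
#'   (recycled by `tibble()`).
#' @export
session_table <- function(subject_id, session_id, session_datetime, interval_label) {
  tbl <- tibble::tibble(
    subject_id = as.character(subject_id),
    session_id = as.character(session_id),
    session_datetime = as.POSIXct(session_datetime, tz = "UTC"),
    interval_label = as.character(interval_label)
  )
  validate_session_table(tbl)
}

validate_session_table <- function(tbl) {
  bad <- setdiff(unique(tbl$interval_label), interval_levels())
  if (length(bad)) {
    stop_validation(paste0(
      "Unknown interval label(s): ", paste(bad, collapse = ", "),
      ". Allowed: ", paste(interval_levels(), collapse = ", ")
    ))
  }
  if (anyDuplicated(tbl[, c("subject_id", "session_id")])) {
    stop_validation("(subject_id, session_id) pairs must be unique in the session table.")
  }
  tbl
}

#' @rdname eeg_tables
#' @param tbl A session or feature table.
#' @param path File path for the CSV.
#' @export
write_session_table <- function(tbl, path) {
  validate_session_table(tbl)
  out <- dplyr::mutate(tbl,
    session_datetime = format(.data$session_datetime, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname eeg_tables
#' @export
read_session_table <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    session_id = readr::col_character(),
    session_datetime = readr::col_character(),
    interval_label = readr::col_character()
  ))
  session_table(
    df$subject_id, df$session_id,
    as.POSIXct(df$session_datetime, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    df$interval_label
  )
}

validate_feature_table <- function(tbl) {
  req <- c("subject_id", "session_id", "feature_name", "value")
  if (!all(req %in% names(tbl))) {
    stop_validation(paste0(
      "Feature table must have columns ",
      paste(req, collapse = ", "), "."
    ))
  }
  bad <- setdiff(unique(tbl$feature_name), feature_levels())
  if (length(bad)) {
    stop_validation(paste0("Unknown feature name(s): ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(tbl[, c("subject_id", "session_id", "feature_name")])) {
    stop_validation("One row per (subject, session, feature) is required.")
  }
  rbp <- tbl$value[startsWith(tbl$feature_name, "rbp_")]
  if (length(rbp) && (any(!is.finite(rbp)) || any(rbp < 0) || any(rbp > 1))) {
    stop_validation("Relative band power values must lie in [0, 1].")
  }
  ipf <- tbl$value[tbl$feature_name == "ipf"]
  if (length(ipf) && (any(!is.finite(ipf)) || any(ipf < 5) || any(ipf > 14))) {
    stop_validation("Individual peak frequency values must lie in [5, 14] Hz.")
  }
  tbl
}

#' @rdname eeg_tables
#' @export
write_feature_table <- function(tbl, path) {
  validate_feature_table(tbl)
  out <- dplyr::arrange(
    tibble::as_tibble(tbl),
    .data$subject_id, .data$session_id,
    match(.data$feature_name, feature_levels())
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname eeg_tables
#' @export
read_feature_table <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    session_id = readr::col_character(),
    feature_name = readr::col_character(),
    value = readr::col_double()
  ))
  validate_feature_table(tibble::as_tibble(df))
}
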