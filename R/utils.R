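# Condition helpers. The pipeline distinguishes usage/configuration errors,
# validation errors (bad inputs), format errors (unreadable files) and
# data-quality errors (e.g. every epoch rejected); the CLI maps these classes
# to exit codes.

stop_validation <- function(msg, ...) {
  abort(msg, class = c("eegretest_validation_error", "eegretest_error"), ...)
}

stop_config <- function(msg, ...) {
  abort(msg, class = c("eegretest_config_error", "eegretest_error"), ...)
}

stop_format <- function(msg, ...) {
  abort(msg, class = c("eegretest_format_error", "eegretest_error"), ...)
}

stop_data_quality <- function(msg, ...) {
  abort(msg, class = c("eegretest_data_quality_error", "eegretest_error"), ...)
}

stop_insufficient_data <- function(msg, ...) {
  abort(msg,
    class = c(
      "eegretest_insufficient_data_error",
      "eegretest_data_quality_error", "eegretest_error"
    ),
    ...
  )
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    stop_validation(sprintf(
      "`%s` must be in [%s, %s], got %s.", name,
      format(lower), format(upper), format(x)
    ))
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 1L) {
  assert_scalar_number(x, name, lower = lower)
  if (x != round(x)) {
    stop_validation(sprintf("`%s` must be an integer, got %s.", name, format(x)))
  }
  invisible(as.integer(x))
}

# Derive a reproducible child seed from a master seed and counters.
# Counter-based so that, e.g., adding subjects never perturbs the streams of
# existing subjects. Kept strictly below 2^31 - 1 for set.seed().
child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) {
    s <- (s * 48271 + as.double(i) + 1) %% 2147483647
  }
  as.integer(s)
}

with_seed_ <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Deterministic polynomial rolling hash of a character string, reported as 8
# hex digits. Used only to fingerprint pipeline configurations in run reports.
config_fingerprint <- function(x) {
  bytes <- as.double(charToRaw(paste(x, collapse = "\n")))
  h <- 5381
  for (b in bytes) {
    h <- (h * 127 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
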