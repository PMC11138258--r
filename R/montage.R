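#' Electrode montages
#'
#' A montage is a tibble with one row per electrode and columns `label`
#' (unique channel name), `x`, `y`, `z` (unit-sphere head coordinates) and
#' `excluded` (logical; `TRUE` for face/neck electrodes that are dropped from
#' whole-brain feature averaging). The packaged default is a 128-channel
#' geodesic-net approximation of which 20 peripheral (lowest) electrodes are
#' excluded, leaving 108 analysis channels.
#'
#' @param path Path to a montage CSV with columns `label,x,y,z,excluded`.
#' @return A tibble of class `eeg_montage`.
#' @examples
#' mont <- default_montage()
#' sum(!mont$excluded) # 108 analysis channels
#' @export
read_montage <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("Montage file not found: ", path))
  df <- readr::read_csv(path,
    col_types = readr::cols(
      label = readr::col_character(),
      x = readr::col_double(), y = readr::col_double(), z = readr::col_double(),
      excluded = readr::col_logical()
    )
  )
  new_montage(df$label, cbind(df$x, df$y, df$z), df$excluded)
}

new_montage <- function(labels, positions, excluded) {
  if (anyDuplicated(labels)) {
    stop_validation("Montage labels must be unique.")
  }
  positions <- as.matrix(positions)
  if (any(!is.finite(positions))) stop_validation("Montage positions must be finite.")
  nrm <- sqrt(rowSums(positions^2))
  if (any(nrm == 0)) stop_validation("Montage positions must be nonzero.")
  positions <- positions / nrm # renormalize onto the unit sphere
  out <- tibble::tibble(
    label = as.character(labels),
    x = positions[, 1], y = positions[, 2], z = positions[, 3],
    excluded = as.logical(excluded)
  )
  class(out) <- c("eeg_montage", class(out))
  out
}

#' @rdname read_montage
#' @export
default_montage <- function() {
  path <- system.file("extdata", "montage_128_synthetic.csv",
    package = "eegretest", mustWork = TRUE
  )
  read_montage(path)
}

#' @rdname read_montage
#' @param montage An `eeg_montage`.
#' @export
analysis_channels <- function(montage) {
  montage$label[!montage$excluded]
}

#' Build a synthetic unit-sphere montage
#'
#' Places `n_channels` electrodes quasi-uniformly on the unit sphere by the
#' Fibonacci lattice and marks the `n_excluded` lowest electrodes (largest
#' polar angle; the face/neck ring of a geodesic net) as excluded from
#' feature averaging. This is a synthetic geometric stand-in for a
#' high-density net layout, adequate for spherical-spline interpolation and
#' for channel-subset bookkeeping.
#'
#' @param n_channels Number of electrodes.
#' @param n_excluded Number of lowest electrodes flagged as excluded.
#' @param prefix Label prefix; labels are `E1..En`.
#' @return An `eeg_montage` tibble.
#' @export
synthetic_montage <- function(n_channels, n_excluded = 0, prefix = "E") {
  n_channels <- assert_count(n_channels, "n_channels", lower = 1)
  n_excluded <- assert_count(n_excluded, "n_excluded", lower = 0)
  if (n_excluded >= n_channels) {
    stop_validation("`n_excluded` must be smaller than `n_channels`.")
  }
  i <- seq_len(n_channels) - 0.5
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n_channels # top of head at z = 1
  r <- sqrt(pmax(0, 1 - z^2))
  th <- golden * i
  pos <- cbind(x = r * cos(th), y = r * sin(th), z = z)
  excluded <- rank(z, ties.method = "first") <= n_excluded
  new_montage(paste0(prefix, seq_len(n_channels)), pos, excluded)
}

write_montage <- function(montage, path) {
  readr::write_csv(tibble::as_tibble(montage)[, c("label", "x", "y", "z", "excluded")], path)
  invisible(path)
}
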