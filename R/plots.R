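#' Plot a reliability table as a classification heatmap
#'
#' Features x intervals tile plot, filled by reliability class
#' (cyan = moderate, yellow = good, green = excellent), with the ICC
#' estimate printed in each cell.
#'
#' @param object A `reliability_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot reliability_table
#' @export
autoplot.reliability_table <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
    reliability_class = factor(.data$reliability_class,
      levels = c("poor", "moderate", "good", "excellent")
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$interval_label,
    y = factor(.data$feature_name, levels = rev(feature_levels()))
  )) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$reliability_class), color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$estimate)), size = 3) +
    ggplot2::scale_fill_manual(
      values = c(
        poor = "grey85", moderate = "cyan3",
        good = "gold", excellent = "springgreen3"
      ),
      drop = FALSE, na.value = "white", name = "Reliability"
    ) +
    ggplot2::labs(x = "Inter-session interval", y = NULL, title = "ICC(A,1) by feature and interval") +
    ggplot2::theme_minimal()
}

#' Plot the per-channel power spectrum
#'
#' @param object A `power_spectrum`.
#' @param channels Optional subset of channel labels.
#' @param ... Unused.
#' @return A ggplot object (log10 PSD vs frequency).
#' @method autoplot power_spectrum
#' @export
autoplot.power_spectrum <- function(object, channels = NULL, ...) {
  labs <- channels %||% object$channel_labels
  idx <- match(labs, object$channel_labels)
  df <- tidyr::expand_grid(channel = labs, i = seq_along(object$freqs))
  df$freq <- object$freqs[df$i]
  df$psd <- as.vector(t(object$absolute[idx, , drop = FALSE]))
  ggplot2::ggplot(df, ggplot2::aes(.data$freq, .data$psd, group = .data$channel)) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::coord_cartesian(xlim = c(0, 90)) +
    ggplot2::labs(
      x = "Frequency (Hz)", y = expression(PSD ~ (mu * V^2 / Hz)),
      title = "Welch power spectral density"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an ICC power curve
#'
#' @inheritParams power_curve
#' @return A ggplot object.
#' @export
plot_power_curve <- function(n, k, rho0, alpha = 0.05, two_sided = FALSE) {
  df <- power_curve(n, k, rho0, alpha = alpha, two_sided = two_sided)
  ggplot2::ggplot(df, ggplot2::aes(.data$rho1, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed") +
    ggplot2::labs(
      x = expression(rho[1] ~ (alternative ~ ICC)), y = "Power",
      title = sprintf("Power of the ICC F-test (n = %d, k = %d, rho0 = %.2f)", n, k, rho0)
    ) +
    ggplot2::theme_minimal()
}
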