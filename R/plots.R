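#' Plot a paired electrogram
#'
#' Both channels against time, faceted.
#'
#' @param object An [egm_pair()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.egm_pair <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("lv", "rv"),
                              names_to = "channel", values_to = "value")
  long$channel <- toupper(long$channel)
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "Time (s)", y = "Amplitude (recorded units)",
                  title = attr(object, "patient"))
}

#' Plot a normalized spectrum with its analysis band
#'
#' @param object An `egm_spectrum` from [welch_psd()].
#' @param harmonics Optional tibble from [detect_harmonics()]; detected
#'   harmonic peaks are marked.
#' @param band Analysis band shaded on the plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.egm_spectrum <- function(object, harmonics = NULL,
                                  band = c(BAND_LO, BAND_HI), ...) {
  p <- ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$freq, .data$pn)) +
    ggplot2::annotate("rect", xmin = band[1], xmax = band[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.08) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::coord_cartesian(xlim = c(0, min(40, max(object$freq)))) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Normalized power (1/Hz)")
  if (!is.null(harmonics)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::filter(harmonics, !is.na(.data$freq)),
      ggplot2::aes(.data$freq, .data$pn), colour = "red", size = 1.5)
  }
  p
}

#' Plot an estimator sweep
#'
#' For Gaussian sample-size sweeps: each information measure against bin
#' width (log scale), one line per sample count — the machine-readable
#' analogue of the bias/plateau diagnostic. For cardiac (single-N) sweeps:
#' measures against bin width per patient.
#'
#' @param object An `egm_sweep` from [sweep_n_and_binwidth()] or
#'   [sweep_binwidth_cardiac()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.egm_sweep <- function(object, ...) {
  kind <- attr(object, "kind")
  df <- as_tibble(object)
  if (identical(kind, "gaussian")) {
    long <- tidyr::pivot_longer(df, c("h_x", "h_y", "h_joint", "mi"),
                                names_to = "measure", values_to = "bits")
    ggplot2::ggplot(long, ggplot2::aes(.data$bin_width, .data$bits,
                                       colour = factor(.data$n))) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
      ggplot2::scale_x_log10() +
      ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y") +
      ggplot2::labs(x = "Bin width", y = "Estimate (bits)", colour = "N")
  } else {
    long <- tidyr::pivot_longer(df, c("h_lv", "h_rv", "h_joint", "mi"),
                                names_to = "measure", values_to = "bits")
    ggplot2::ggplot(long, ggplot2::aes(.data$bin_width, .data$bits,
                                       group = .data$patient)) +
      ggplot2::geom_line(alpha = 0.6) +
      ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y") +
      ggplot2::labs(x = "Bin width (SD units)", y = "Estimate (bits)")
  }
}
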