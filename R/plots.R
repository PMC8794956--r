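#' Plot mean spectra with confidence bands
#'
#' @param ms Tibble from [mean_spectrum_with_ci()].
#' @return A ggplot: mean dB power per frequency, ribbon = Bonferroni CI,
#'   faceted by channel, colored by condition.
#' @export
plot_mean_spectrum <- function(ms) {
  ggplot2::ggplot(ms, ggplot2::aes(x = .data$freq, y = .data$mean_db,
                                   color = .data$condition,
                                   fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25, linewidth = 0) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Power (dB)",
                  title = sprintf("Mean spectra with %s%% CI",
                                  attr(ms, "level_percent"))) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_pca Scree plot of explained variance.
#' @param object Fitted object.
#' @export
autoplot.ni_pca <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(dplyr::filter(td, .data$component <= 100),
                  ggplot2::aes(.data$component, .data$cumulative_evf)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed") +
    ggplot2::labs(x = "Principal component", y = "Cumulative variance fraction") +
    ggplot2::theme_minimal()
}

#' @describeIn evaluate_ensemble Accuracy distribution per individual and
#'   period, null ensembles shown alongside.
#' @param object An `ni_trace`.
#' @param ... Unused.
#' @export
autoplot.ni_trace <- function(object, ...) {
  d <- dplyr::mutate(object,
    group = paste0(.data$individual, ifelse(.data$null, " (null)", "")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$accuracy,
                                  color = .data$null)) +
    ggplot2::geom_jitter(width = 0.2, size = 0.4, alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::facet_grid(ggplot2::vars(.data$method), ggplot2::vars(.data$period)) +
    ggplot2::labs(x = "Individual", y = "Balanced accuracy", color = "Null") +
    ggplot2::theme_minimal()
}
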