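# ggplot2 visualizations for each result type.

mps_long <- function(x, value_field) {
  expand.grid(spectral = x$spectral_modulations,
              temporal = x$temporal_modulations) %>%
    as_tibble() %>%
    mutate(value = as.numeric(x[[value_field]]))
}

#' Plot a modulation power spectrum
#'
#' @param object A `cry_mps`.
#' @param db Display in dB (default) rather than raw amplitude.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cry_mps <- function(object, db = TRUE, ...) {
  d <- mps_long(object, "amplitude")
  if (db) d$value <- 20 * log10(d$value + 1e-12)
  ggplot2::ggplot(d, ggplot2::aes(.data$temporal, .data$spectral,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = if (db) "dB" else "amplitude") +
    ggplot2::labs(x = "temporal modulation (Hz)",
                  y = "spectral modulation (cyc/kHz)") +
    ggplot2::theme_minimal()
}

#' Plot an MPS difference map
#'
#' @param object A `cry_mps_diff`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cry_mps_diff <- function(object, ...) {
  d <- mps_long(object, "values")
  ggplot2::ggplot(d, ggplot2::aes(.data$temporal, .data$spectral,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(name = "dB", low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = "temporal modulation (Hz)",
                  y = "spectral modulation (cyc/kHz)") +
    ggplot2::theme_minimal()
}

#' Plot a spectrogram
#'
#' @param object A `cry_spectrogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cry_spectrogram <- function(object, ...) {
  d <- expand.grid(freq = object$freq, time = object$times) %>%
    as_tibble() %>%
    mutate(db = as.numeric(object$db))
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$freq, fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot the per-baby acoustic map
#'
#' One point per baby per condition in the PC1-PC2 plane, with the condition
#' centroids marked.
#'
#' @param object An `acoustic_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.acoustic_map <- function(object, ...) {
  cen <- attr(object, "centroids")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$PC1, .data$PC2, colour = .data$condition)) +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = cen, shape = 4, size = 4, stroke = 1.5) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::theme_minimal()
}

#' Plot identity-classification confusion matrix
#'
#' @param object An `identity_report`.
#' @param ... Unused.
#' @return A ggplot heat map of mean posterior probabilities.
#' @export
autoplot.identity_report <- function(object, ...) {
  tidy(object) %>%
    ggplot2::ggplot(ggplot2::aes(.data$predicted_baby, .data$true_baby,
                                 fill = .data$posterior)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "posterior", limits = c(0, 1)) +
    ggplot2::labs(x = "predicted baby", y = "true baby",
                  subtitle = sprintf("%s / %s / %s: %.1f%% mean diagonal (chance %.1f%%)",
                                     object$model, object$space, object$scheme,
                                     100 * object$mean_diag_posterior,
                                     100 * object$chance)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}

#' Plot acoustic-space trajectories
#'
#' Arrows from each baby's discomfort mean (base) to its pain mean (tip),
#' with the condition-discriminant projection on x and a PC coordinate on y.
#'
#' @param object A `trajectory_stats`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trajectory_stats <- function(object, ...) {
  ggplot2::ggplot(object$arrows) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "cm")),
      colour = "grey30") +
    ggplot2::labs(x = "condition discriminant projection",
                  y = sprintf("PC%d", object$pc)) +
    ggplot2::theme_minimal()
}

#' Plot listener-model posterior summaries
#'
#' @param object A `listener_fit`.
#' @param ... Unused.
#' @return A ggplot of medians and 95% credible intervals.
#' @export
autoplot.listener_fit <- function(object, ...) {
  ggplot2::ggplot(object$summaries,
                  ggplot2::aes(.data$quantity, .data$median)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lower,
                                        ymax = .data$ci_upper), width = 0.2) +
    ggplot2::geom_hline(yintercept = object$chance, linetype = "dotted") +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "posterior (probability scale)", x = NULL) +
    ggplot2::theme_minimal()
}
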