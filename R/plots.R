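#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an SMA fit
#'
#' Scatter of the fitted data with the SMA (or OLS) line and an optional
#' dotted reference line of slope `reference_slope` through the data centroid
#' (the inverse-proportionality expectation when -1).
#'
#' @param object An `sma_fit` object.
#' @param reference_slope Optional slope for a dotted reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sma_fit <- function(object, reference_slope = NULL, ...) {
  d <- tibble::tibble(x = object$x, y = object$y)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope) +
    ggplot2::labs(
      x = object$x_label, y = object$y_label,
      subtitle = sprintf("%s slope = %.3f [%.3f, %.3f], r2 = %.3f",
                         toupper(object$method), object$slope,
                         object$ci_lower, object$ci_upper, object$r_squared)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(reference_slope)) {
    ref_int <- mean(object$y) - reference_slope * mean(object$x)
    p <- p + ggplot2::geom_abline(intercept = ref_int, slope = reference_slope,
                                  linetype = "dotted")
  }
  p
}

#' Plot the trade-off variants
#'
#' One panel per body-size-correction variant, each with its SMA line and the
#' dotted slope -1 reference through the centroid.
#'
#' @param object A `tradeoff_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tradeoff_report <- function(object, ...) {
  d <- purrr::imap_dfr(object$fits, function(f, nm) {
    tibble::tibble(variant = nm, x = f$x, y = f$y)
  })
  lines <- purrr::imap_dfr(object$fits, function(f, nm) {
    tibble::tibble(variant = nm, intercept = f$intercept, slope = f$slope,
                   ref_intercept = mean(f$y) + mean(f$x), ref_slope = -1)
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(intercept = .data$intercept,
                                      slope = .data$slope)) +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(intercept = .data$ref_intercept,
                                      slope = .data$ref_slope),
                         linetype = "dotted") +
    ggplot2::facet_wrap(~variant, scales = "free_y") +
    ggplot2::labs(x = "log10 spore mass (ug)", y = "log10 (corrected) spore output") +
    ggplot2::theme_minimal()
}

#' Violin plot of offspring-size distributions across taxa
#'
#' @param comparison A `taxa_comparison` from [compare_taxa()].
#' @param log10_axis Show sizes on a log10 axis (recommended: the
#'   distributions span orders of magnitude).
#' @return A ggplot object.
#' @export
plot_taxa_comparison <- function(comparison, log10_axis = TRUE) {
  stopifnot(inherits(comparison, "taxa_comparison"))
  p <- ggplot2::ggplot(comparison$data,
                       ggplot2::aes(x = .data$taxon, y = .data$size)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = NULL, y = "offspring size") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  if (isTRUE(log10_axis)) p <- p + ggplot2::scale_y_log10()
  p
}
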