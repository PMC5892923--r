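#' Scatter plot of a correlation result
#'
#' Shows the paired values behind a [correlate_fc_with_spike()] or
#' [correlate_cluster_with_external()] result with the least-squares line
#' and the fitted coefficients in the subtitle.
#'
#' @param object A `dige_correlation` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dige_correlation
#' @export
autoplot.dige_correlation <- function(object, ...) {
  df <- tibble::tibble(x = object$x, y = object$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 3, colour = "steelblue4") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = 2) +
    ggplot2::labs(
      title = sprintf("Pearson r = %.2f (p = %.3g), Kendall tau = %.2f (p = %.3g)",
                      object$r, object$p, object$tau, object$tau_p),
      subtitle = sprintf("y = %.3g x %+.3g, n = %d",
                         object$slope, object$intercept, object$n),
      x = "fold change (low/high)", y = "Δspike"
    ) +
    ggplot2::theme_minimal()
}

#' Volcano plot of cross-patient spot tests
#'
#' Mean natural-log fold change against `-log10(p)` for every tested spot,
#' with the significance thresholds drawn and significant spots
#' highlighted.
#'
#' @param tests Results of [test_spots()].
#' @param alpha,fc_min Thresholds to draw.
#' @return A ggplot.
#' @export
plot_volcano <- function(tests, alpha = 0.05, fc_min = 1.25) {
  df <- tests |>
    dplyr::filter(!.data$degenerate) |>
    dplyr::mutate(neg_log10_p = -log10(.data$p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_ln_fc, y = .data$neg_log10_p,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 3) +
    ggplot2::geom_vline(xintercept = c(-log(fc_min), log(fc_min)), linetype = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "mean ln fold change (high/low)", y = "-log10 p",
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Per-patient protein totals by condition
#'
#' Bar chart of a protein's summed isoform abundance per patient and
#' spike-frequency condition, the standard display for GFAP-style roll-up
#' totals.
#'
#' @param totals Output of [aggregate_isoforms()].
#' @param title Plot title.
#' @return A ggplot.
#' @export
plot_protein_totals <- function(totals, title = "Protein total by sample") {
  ggplot2::ggplot(totals,
                  ggplot2::aes(x = .data$patient_id, y = .data$total,
                               fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::scale_fill_manual(values = c(high = "firebrick", low = "steelblue")) +
    ggplot2::labs(title = title, x = NULL,
                  y = "total normalized volume (volume units)") +
    ggplot2::theme_minimal()
}
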