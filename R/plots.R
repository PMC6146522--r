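# ggplot2 displays for the main result types.

#' Rainfall plot of inter-SNV distances
#'
#' One point per adjacent SNV pair: genomic position of the right-hand SNV
#' against the (log-scaled) distance to the previous SNV, coloured by whether
#' the exponential-model p-value falls below the clustering cutoff. Dense
#' clusters appear as low-lying runs of significant points.
#'
#' @param object A [fit_distance_model()] object.
#' @param alpha_distance Cutoff on `p_exp` used for colouring.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot distance_model
#' @export
autoplot.distance_model <- function(object, alpha_distance = 0.01, ...) {
  d <- dplyr::mutate(object$distances,
                     significant = .data$p_exp < alpha_distance)
  ggplot2::ggplot(d, ggplot2::aes(.data$end_pos, .data$distance + 1,
                                  colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "inter-SNV distance + 1 (bp)",
                  colour = sprintf("p_exp < %g", alpha_distance)) +
    ggplot2::theme_minimal()
}

#' Case-permutation ratio curve plot
#'
#' CPR against the p-value threshold, one line per permutation scheme, with
#' the 0.5 no-signal reference. A flat band around 0.5 is the signature of a
#' phenotype with no group-specific genetic signal.
#'
#' @param object A [cpr_curve()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cpr_curve
#' @export
autoplot.cpr_curve <- function(object, ...) {
  perm <- tibble::as_tibble(object[!object$is_case, ])
  ggplot2::ggplot(perm, ggplot2::aes(.data$threshold, .data$cpr,
                                     group = .data$scheme_id,
                                     colour = factor(.data$scheme_id))) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "p-value threshold", y = "case-permutation ratio",
                  colour = "permutation") +
    ggplot2::theme_minimal()
}

#' Heatmap of pairwise base-weight correlations
#'
#' @param correlations Tibble from [weight_correlation_matrix()].
#' @return A ggplot tile map of Pearson r per sample pair.
#' @export
plot_weight_correlation <- function(correlations) {
  both <- dplyr::bind_rows(
    correlations,
    dplyr::rename(correlations, sample_a = "sample_b", sample_b = "sample_a")
  )
  ggplot2::ggplot(both, ggplot2::aes(.data$sample_a, .data$sample_b,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$r)), size = 3) +
    ggplot2::scale_fill_gradient(limits = c(NA, 1), low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal()
}
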