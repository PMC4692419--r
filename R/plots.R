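# ggplot2 visualizations for the result objects.

#' Volcano-style plot of differential results
#'
#' Median difference between groups (stable minus CIPN, on the normalized
#' ln scale) against -log10(q), with selected features highlighted.
#'
#' @param object A `track_diff` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot track_diff
#' @export
autoplot.track_diff <- function(object, ...) {
  df <- object$results %>%
    mutate(delta = .data$median_group2 - .data$median_group1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta,
                                   y = -log10(pmax(.data$q_value, 1e-12)),
                                   colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(object$q_threshold),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "median difference (stable - CIPN, ln scale)",
      y = expression(-log[10](q)),
      colour = sprintf("q < %g", object$q_threshold),
      title = sprintf("%s track, %s", object$track, object$timepoint)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of the 2-D PCA scores by phenotype group
#'
#' @param object A `pca_sep` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pca_sep
#' @export
autoplot.pca_sep <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$pc1, y = .data$pc2,
                               colour = .data$group)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = if (length(object$var_explained) > 1)
        sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2]) else "PC2",
      title = sprintf("separation index %.2f", object$separation)) +
    ggplot2::theme_minimal()
}

#' Membership plot of a combined dual-track signature
#'
#' One tile per protein and track, showing which track(s) contributed each
#' combined-signature member.
#'
#' @param object A `signature` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot signature
#' @export
autoplot.signature <- function(object, ...) {
  df <- tidy(object) %>%
    tidyr::pivot_longer(c("in_protein_track", "in_peptide_track"),
                        names_to = "track", values_to = "member") %>%
    mutate(track = ifelse(.data$track == "in_protein_track",
                          "protein (spectral counts)",
                          "peptide (peak areas)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$track, y = .data$protein,
                                   fill = .data$member)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey90",
                                          `TRUE` = "steelblue")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "selected",
                  title = sprintf("combined signature: %d proteins",
                                  length(object$combined))) +
    ggplot2::theme_minimal()
}
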