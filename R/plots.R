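#' @describeIn roc_auc ROC curve plot (sensitivity against 1 - specificity)
#'   with the AUC in the subtitle.
#' @param object An `sbna_roc` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.sbna_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_step(linewidth = 0.8, colour = "#6a3d9a") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = "ROC curve",
                  subtitle = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Score distributions by pathogenicity label
#'
#' Box-and-jitter plot of a chosen score column across label groups, the
#' standard visual check that pathogenic variants score above benign ones.
#'
#' @param scored Scored variant tibble ([score_variants()]) with a `label`
#'   column.
#' @param score Column to plot (default `modified`).
#' @return A ggplot object.
#' @export
plot_score_groups <- function(scored, score = "modified") {
  d <- scored %>%
    filter(.data$label != "unlabeled", !is.na(.data[[score]]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data[[score]],
                                  fill = .data$label)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::scale_fill_manual(values = c(benign = "#33a02c",
                                          vus = "#ff7f00",
                                          pathogenic = "#e31a1c"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = score) +
    ggplot2::theme_minimal()
}

#' Network score along the sequence
#'
#' Per-residue network score against residue number, highlighting the
#' topologically constrained stretches of the chain.
#'
#' @param scores Score table from [sbna_scores()].
#' @return A ggplot object.
#' @export
plot_network_scores <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$resno,
                                       y = .data$network_score)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$bridging),
                        colour = "#1f78b4", alpha = 0.8) +
    ggplot2::scale_size_continuous(range = c(0.8, 3.5)) +
    ggplot2::labs(x = "Residue number", y = "Network score",
                  size = "Bridging") +
    ggplot2::theme_minimal()
}
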