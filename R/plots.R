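#' @method autoplot lnc_ordering
#' @export
autoplot.lnc_ordering <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$v,
                                  colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "pseudo-time rank", y = "differential intensity V",
                  colour = NULL,
                  title = sprintf("Pseudo-time ordering (fc* = %.2f, p* = %.4f)",
                                  object$fc_star, object$p_star)) +
    ggplot2::theme_minimal()
}

#' @method autoplot lnc_roc
#' @export
autoplot.lnc_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @method autoplot lnc_discern
#' @export
autoplot.lnc_discern <- function(object, ...) {
  ggplot2::ggplot(object$projections,
                  ggplot2::aes(x = .data$set, y = .data$projection,
                               colour = .data$set)) +
    ggplot2::geom_jitter(width = 0.1, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "projection on w*",
                  title = sprintf("Discerning score DS = %.3f", object$ds)) +
    ggplot2::theme_minimal()
}

#' Bar chart of enriched-pathway counts per bin, category and direction
#'
#' @param category_counts Output of [categorize_counts()].
#' @return A ggplot object.
#' @export
plot_category_counts <- function(category_counts) {
  ggplot2::ggplot(category_counts,
                  ggplot2::aes(x = factor(.data$bin), y = .data$n_pathways,
                               fill = .data$category)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(x = "bin", y = "enriched pathways", fill = NULL) +
    ggplot2::theme_minimal()
}
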