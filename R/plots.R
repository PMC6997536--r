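#' Plot a ROC curve
#'
#' Sensitivity against specificity on a reversed specificity axis, with
#' the chance diagonal and the high-specificity band boundary.
#'
#' @param object A `roc_curve` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_abline(intercept = 1, slope = 1, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_vline(xintercept = object$spec_min,
                        linetype = "dashed", colour = "grey70") +
    ggplot2::geom_path() +
    ggplot2::scale_x_reverse(limits = c(1, 0)) +
    ggplot2::labs(x = "Specificity", y = "Sensitivity",
                  title = sprintf("ROC (AUC = %.4f, pAUC = %.4f)",
                                  object$auc, object$pauc)) +
    ggplot2::theme_minimal()
}

#' Plot a precision-recall curve
#'
#' @param object A `pr_curve` object.
#' @param ... Unused.
#' @return A ggplot object; the dotted line marks the prevalence (the
#'   precision of a random ranking).
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_hline(yintercept = object$prevalence,
                        linetype = "dotted", colour = "grey50") +
    ggplot2::geom_path() +
    ggplot2::labs(x = "Recall", y = "Precision",
                  title = sprintf("PR (AUC = %.4f)", object$pr_auc)) +
    ggplot2::theme_minimal()
}

#' Plot the cumulative F-score curve of a ranking
#'
#' F-score at every top-fraction cutoff of the ranked list.
#'
#' @param x A `pr_curve` object.
#' @return A ggplot object.
#' @export
plot_f_curve <- function(x) {
  stopifnot(inherits(x, "pr_curve"))
  ggplot2::ggplot(x$f_curve,
                  ggplot2::aes(x = .data$fraction, y = .data$f)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Top fraction of ranked interactions", y = "F-score",
                  title = sprintf("Cumulative F-score (mean F = %.4f)",
                                  x$mean_f)) +
    ggplot2::theme_minimal()
}

#' Plot per-method metric distributions across replicates
#'
#' @param object A `method_comparison` object.
#' @param metric Metric column to plot; default `"roc_auc"`.
#' @param ... Unused.
#' @return A ggplot object (one box per method over replicates).
#' @export
autoplot.method_comparison <- function(object, metric = "roc_auc", ...) {
  d <- object$metrics
  stopifnot(metric %in% names(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method,
                                  y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}
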