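#' Tidy a ROC curve into its points
#'
#' @param x A `roc_curve` object.
#' @param ... Unused.
#' @return A tibble of (specificity, sensitivity) points.
#' @export
tidy.roc_curve <- function(x, ...) x$points

#' One-row summary of a ROC curve
#'
#' @param x A `roc_curve` object.
#' @param ... Unused.
#' @return A tibble with `roc_auc`, `pauc`, `sens_at_spec`, `spec_min`,
#'   `n_pos`, `n_neg`.
#' @export
glance.roc_curve <- function(x, ...) {
  tibble::tibble(roc_auc = x$auc, pauc = x$pauc,
                 sens_at_spec = x$sens_at_spec_min, spec_min = x$spec_min,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy a PR curve into its points
#'
#' @param x A `pr_curve` object.
#' @param ... Unused.
#' @return A tibble of (recall, precision) points.
#' @export
tidy.pr_curve <- function(x, ...) x$points

#' One-row summary of a PR curve
#'
#' @param x A `pr_curve` object.
#' @param ... Unused.
#' @return A tibble with `pr_auc`, `mean_f`, the F values at the requested
#'   top fractions, `prevalence`, and `n`.
#' @export
glance.pr_curve <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(pr_auc = x$pr_auc, mean_f = x$mean_f),
    tibble::as_tibble(as.list(x$f_at_fraction)),
    tibble::tibble(prevalence = x$prevalence, n = x$n)
  )
}

#' Per-replicate metrics of a method comparison
#'
#' @param x A `method_comparison` object.
#' @param ... Unused.
#' @return The replicate x method metric tibble.
#' @export
tidy.method_comparison <- function(x, ...) x$metrics

#' Test summaries of a method comparison
#'
#' @param x A `method_comparison` object.
#' @param ... Unused.
#' @return One row per tested metric: ANOVA F and p plus the smallest
#'   adjusted p-value among the contrasts against the control.
#' @export
glance.method_comparison <- function(x, ...) {
  ph <- x$posthoc |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(min_adj_p = min(.data$adj.p.value),
                     n_significant = sum(.data$significant),
                     .groups = "drop")
  dplyr::left_join(
    dplyr::select(x$anova, "metric", "statistic", "df", "df_error",
                  "p.value"),
    ph, by = "metric")
}
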