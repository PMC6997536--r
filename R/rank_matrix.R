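#' Build a normalized rank matrix from per-source prediction lists
#'
#' Converts the prediction lists of several sources into a matrix of
#' normalized relative ranks over the union of all predicted interactions.
#' Within each source, entries are ordered best-to-worst according to the
#' source's score direction, tied scores receive midranks, and ranks are
#' divided by that source's list length so the worst untied entry gets
#' exactly 1. Interactions absent from a source are imputed at the maximum
#' relative rank, 1.
#'
#' @param predictions A data frame of predictions in long form with columns
#'   `source`, `mirna`, `gene` and either `score` or `rank`. When a `rank`
#'   column is supplied it is treated as a better-is-lower score.
#' @param directions Optional named character vector mapping source names to
#'   `"lower"` (smaller score is better, the default) or `"higher"`.
#' @return A tibble of class `rank_matrix` with columns `mirna`, `gene`, and
#'   one numeric column per source holding normalized relative ranks in
#'   (0, 1], with absent interactions at exactly 1. The attribute `midrank`
#'   holds the per-source (mid)ranks with `NA` where an interaction is not
#'   listed; `sources` and `list_sizes` record the source names and their
#'   list lengths.
#' @examples
#' preds <- tibble::tibble(
#'   source = rep(c("a", "b"), each = 3),
#'   mirna  = "hsa-miR-16-5p",
#'   gene   = c("G1", "G2", "G3", "G2", "G3", "G4"),
#'   score  = c(0.1, 0.5, 0.9, 2, 1, 3)
#' )
#' build_rank_matrix(preds)
#' @export
build_rank_matrix <- function(predictions, directions = NULL) {
  stopifnot(is.data.frame(predictions))
  score_col <- if ("score" %in% names(predictions)) "score" else "rank"
  need <- c("source", "mirna", "gene", score_col)
  miss <- setdiff(need, names(predictions))
  if (length(miss) > 0) {
    abort(paste0("`predictions` is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(predictions) == 0) abort("`predictions` has no rows")
  if (!all(is.finite(predictions[[score_col]]))) {
    abort("non-finite score in `predictions`")
  }

  src_names <- unique(as.character(predictions$source))
  if (is.null(directions)) {
    directions <- stats::setNames(rep("lower", length(src_names)), src_names)
  }
  directions <- check_directions(directions, src_names)

  dup <- predictions |>
    dplyr::count(.data$source, .data$mirna, .data$gene) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate interaction within source '%s': %s :: %s",
                  dup$source[1], dup$mirna[1], dup$gene[1]))
  }

  ranked <- predictions |>
    dplyr::mutate(
      source = as.character(.data$source),
      .s = unname(ifelse(directions[.data$source] == "higher",
                         -.data[[score_col]], .data[[score_col]]))
    ) |>
    dplyr::group_by(.data$source) |>
    dplyr::mutate(
      .midrank = rank(.data$.s, ties.method = "average"),
      .nr = .data$.midrank / dplyr::n()
    ) |>
    dplyr::ungroup()

  norm <- ranked |>
    dplyr::select("mirna", "gene", "source", ".nr") |>
    tidyr::pivot_wider(names_from = "source", values_from = ".nr") |>
    dplyr::arrange(.data$mirna, .data$gene)
  mid <- ranked |>
    dplyr::select("mirna", "gene", "source", ".midrank") |>
    tidyr::pivot_wider(names_from = "source", values_from = ".midrank") |>
    dplyr::arrange(.data$mirna, .data$gene)

  # keep source column order stable regardless of first appearance
  norm <- norm[, c("mirna", "gene", src_names)]
  mid  <- mid[, c("mirna", "gene", src_names)]

  midmat <- as.matrix(mid[, src_names, drop = FALSE])
  for (s in src_names) {
    norm[[s]] <- ifelse(is.na(norm[[s]]), 1, norm[[s]])
  }

  sizes <- predictions |>
    dplyr::count(.data$source) |>
    tibble::deframe()
  out <- tibble::new_tibble(norm, class = "rank_matrix")
  attr(out, "sources") <- src_names
  attr(out, "list_sizes") <- sizes[src_names]
  attr(out, "midrank") <- midmat
  out
}

check_directions <- function(directions, src_names) {
  if (is.null(names(directions)) && length(directions) == length(src_names)) {
    names(directions) <- src_names
  }
  directions <- directions[src_names]
  if (anyNA(directions)) {
    abort("`directions` must name every source present in `predictions`")
  }
  if (!all(directions %in% c("lower", "higher"))) {
    abort('each direction must be "lower" or "higher"')
  }
  directions
}

#' @export
print.rank_matrix <- function(x, ...) {
  srcs <- attr(x, "sources")
  cat(sprintf("<rank_matrix> %d interactions x %d sources (%s)\n",
              nrow(x), length(srcs), paste(srcs, collapse = ", ")))
  NextMethod()
  invisible(x)
}

# Numeric matrix of normalized ranks (absent = 1) from a rank_matrix tibble.
rank_matrix_values <- function(rm) {
  srcs <- attr(rm, "sources")
  if (is.null(srcs)) {
    abort("`matrix` must be a rank_matrix built by build_rank_matrix()")
  }
  as.matrix(rm[, srcs, drop = FALSE])
}
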