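#' Rank pathways by the proportion of member genes a miRNA targets
#'
#' For the predicted targets of a single miRNA, scores each pathway by the
#' proportion of its member genes that are confidently targeted — i.e.
#' appear among the miRNA's predictions with an aggregated score at or
#' below the threshold — and sorts pathways by that proportion,
#' descending (ties broken by pathway id). Each pathway also carries the
#' number of those targeted member genes whose interaction with the miRNA
#' is experimentally validated.
#'
#' @param targets An [aggregate_ranks()]-style data frame of predictions
#'   for exactly one miRNA (columns `mirna`, `gene`, `score`).
#' @param pathways A [read_gmt()] pathway tibble (`pathway_id`, `name`,
#'   `genes` list-column).
#' @param labels Optional validated-pair data frame (`mirna`, `gene`).
#' @param threshold Score cutoff defining a confident target; default
#'   0.05.
#' @param denominator `"pathway"` (default): divide by all member genes of
#'   the pathway; `"universe"`: divide by member genes that appear in
#'   `targets` at all, restricting the proportion to the predicted
#'   universe.
#' @return A tibble with one row per pathway: `pathway_id`, `name`,
#'   `n_genes` (the denominator used), `n_targeted`, `proportion`,
#'   `n_validated`, sorted by descending proportion.
#' @export
rank_pathways <- function(targets, pathways, labels = NULL,
                          threshold = 0.05,
                          denominator = c("pathway", "universe")) {
  denominator <- match.arg(denominator)
  stopifnot(is.data.frame(targets),
            all(c("mirna", "gene", "score") %in% names(targets)))
  if (nrow(targets) == 0) abort("`targets` is empty")
  mirna <- unique(targets$mirna)
  if (length(mirna) != 1) {
    abort("`targets` must concern exactly one miRNA")
  }
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1]")
  if (any(lengths(pathways$genes) == 0)) abort("empty pathway in table")

  hits <- targets$gene[targets$score <= threshold]
  validated <- if (is.null(labels)) character(0) else {
    labels$gene[labels$mirna == mirna]
  }
  out <- pathways |>
    dplyr::mutate(
      n_genes = dplyr::case_when(
        denominator == "pathway" ~ lengths(.data$genes),
        TRUE ~ vapply(.data$genes, function(g) {
          sum(g %in% targets$gene)
        }, integer(1))
      ),
      n_targeted = vapply(.data$genes, function(g) {
        sum(g %in% hits)
      }, integer(1)),
      proportion = ifelse(.data$n_genes == 0, 0,
                          .data$n_targeted / .data$n_genes),
      n_validated = vapply(.data$genes, function(g) {
        sum(g %in% intersect(hits, validated))
      }, integer(1))
    ) |>
    dplyr::select("pathway_id", "name", "n_genes", "n_targeted",
                  "proportion", "n_validated") |>
    dplyr::arrange(dplyr::desc(.data$proportion), .data$pathway_id)
  out
}

#' Write a pathway ranking as TSV
#'
#' @param report A [rank_pathways()] tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pathway_report <- function(report, path) {
  writeLines(c("pathway_id\tname\tn_genes\tn_targeted\tproportion\tn_validated",
               sprintf("%s\t%s\t%d\t%d\t%.6f\t%d", report$pathway_id,
                       report$name, report$n_genes, report$n_targeted,
                       report$proportion, report$n_validated)), path)
  invisible(path)
}
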