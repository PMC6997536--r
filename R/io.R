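#' Read a prediction list TSV
#'
#' Reads one source's predictions from a tab-separated file with header
#' columns `mirna`, `gene` and either `score` or `rank`. Validation is
#' strict: a malformed header, a non-numeric score, or a duplicated
#' (mirna, gene) pair is an error naming the offending line, because a
#' silently dropped or misparsed row would misalign scores and labels
#' downstream.
#'
#' @param path Path to the TSV file.
#' @param source Source name attached to the result; default: file name
#'   without extension.
#' @return A tibble with columns `source`, `mirna`, `gene`, and `score`
#'   (or `rank`), suitable for [build_rank_matrix()] after row-binding
#'   sources.
#' @export
read_predictions <- function(path, source = NULL) {
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  value_col <- intersect(c("score", "rank"), hdr)
  if (!all(c("mirna", "gene") %in% hdr) || length(value_col) == 0) {
    abort(sprintf(
      "%s: header must contain mirna, gene and score (or rank); found: %s",
      path, paste(hdr, collapse = ", ")))
  }
  d <- utils::read.delim(path, sep = "\t", colClasses = "character",
                         check.names = FALSE)
  val <- suppressWarnings(as.numeric(d[[value_col[1]]]))
  bad <- which(!is.finite(val))
  if (length(bad) > 0) {
    abort(sprintf("%s: non-numeric %s '%s' at line %d", path, value_col[1],
                  d[[value_col[1]]][bad[1]], bad[1] + 1L))
  }
  key <- paste(d$mirna, d$gene, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort(sprintf("%s: duplicate interaction %s :: %s at line %d", path,
                  d$mirna[dup[1]], d$gene[dup[1]], dup[1] + 1L))
  }
  out <- tibble::tibble(
    source = source %||% sub("\\.[^.]*$", "", basename(path)),
    mirna = d$mirna, gene = d$gene)
  out[[value_col[1]]] <- val
  out
}

#' Read several prediction lists plus their sidecar configuration
#'
#' The JSON sidecar (as written by [make_fixture()]) declares each
#' source's file, name and sort direction. Returns everything
#' [build_rank_matrix()] needs.
#'
#' @param config_path Path to the sources JSON file; source files are
#'   resolved relative to it.
#' @return A list with `predictions` (long tibble over all sources) and
#'   `directions` (named character vector).
#' @export
read_sources <- function(config_path) {
  cfg <- jsonlite::read_json(config_path)
  base <- dirname(config_path)
  preds <- purrr::map_dfr(cfg$sources, function(s) {
    read_predictions(file.path(base, s$file), source = s$name)
  })
  dirs <- vapply(cfg$sources, function(s) s$direction, character(1))
  names(dirs) <- vapply(cfg$sources, function(s) s$name, character(1))
  list(predictions = preds, directions = dirs)
}

#' Read a validated-interaction label file
#'
#' Two tab-separated columns, `mirna` and `gene`, one experimentally
#' validated pair per line (the export format of validated-interaction
#' catalogues). Duplicate pairs are an error naming the line.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `mirna`, `gene`.
#' @export
read_labels <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (!all(c("mirna", "gene") %in% hdr)) {
    abort(sprintf("%s: header must contain mirna and gene", path))
  }
  d <- utils::read.delim(path, sep = "\t", colClasses = "character")
  dup <- which(duplicated(paste(d$mirna, d$gene, sep = "\r")))
  if (length(dup) > 0) {
    abort(sprintf("%s: duplicate pair at line %d", path, dup[1] + 1L))
  }
  tibble::tibble(mirna = d$mirna, gene = d$gene)
}

#' Attach 0/1 validation labels to a scored list
#'
#' @param results A data frame with `mirna` and `gene` columns (e.g. an
#'   [aggregate_ranks()] output).
#' @param labels A data frame of validated pairs (`mirna`, `gene`).
#' @return `results` with an integer `label` column appended.
#' @export
label_interactions <- function(results, labels) {
  lab <- dplyr::distinct(labels, .data$mirna, .data$gene) |>
    dplyr::mutate(label = 1L)
  dplyr::left_join(results, lab, by = c("mirna", "gene")) |>
    dplyr::mutate(label = dplyr::coalesce(.data$label, 0L))
}

#' Write an aggregated prediction table as TSV
#'
#' Columns: mirna, gene, score, rank, n_sources, then one per-source rank
#' column (empty when the source did not list the interaction). Scores are
#' written with six decimals and per-source midranks with a minimal
#' decimal representation, so output is byte-stable across runs.
#'
#' @param results An `aggregation` tibble from [aggregate_ranks()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(results, path) {
  rank_cols <- grep("^rank_", names(results), value = TRUE)
  fmt_rank <- function(x) ifelse(is.na(x), "",
                                 sub("\\.?0+$", "", sprintf("%.1f", x)))
  body <- sprintf("%s\t%s\t%.6f\t%d\t%d", results$mirna, results$gene,
                  results$score, results$rank, results$n_sources)
  for (col in rank_cols) {
    body <- paste(body, fmt_rank(results[[col]]), sep = "\t")
  }
  writeLines(c(paste(c("mirna", "gene", "score", "rank", "n_sources",
                       rank_cols), collapse = "\t"), body), path)
  invisible(path)
}

#' Read a GMT gene-set file of pathways
#'
#' Standard GMT dialect: one pathway per line, tab-separated fields
#' `id`, `description`, then member gene ids. Duplicate pathway ids are an
#' error naming the line.
#'
#' @param path Path to the GMT file.
#' @return A tibble with columns `pathway_id`, `name`, and a list-column
#'   `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short) > 0) {
    abort(sprintf("%s: line %d has fewer than 3 fields", path, short[1]))
  }
  ids <- vapply(parts, `[[`, character(1), 1)
  dup <- which(duplicated(ids))
  if (length(dup) > 0) {
    abort(sprintf("%s: duplicate pathway id '%s' at line %d", path,
                  ids[dup[1]], dup[1]))
  }
  tibble::tibble(
    pathway_id = ids,
    name = vapply(parts, `[[`, character(1), 2),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
}

#' Build an identifier alias map
#'
#' An alias map sends legacy or synonymous identifiers to their canonical
#' form (e.g. retired miRNA names to the current nomenclature release, or
#' gene symbols to stable numeric gene ids). Construction enforces the two
#' map invariants: no alias maps to two different canonical ids, and every
#' canonical id maps to itself.
#'
#' @param aliases A data frame with columns `alias` and `canonical`, or a
#'   path to a two-column TSV with that header.
#' @param kind `"mirna"` (matching will be case-insensitive) or `"gene"`.
#' @return A tibble of class `alias_map` with columns `alias`,
#'   `canonical`.
#' @export
alias_map <- function(aliases, kind = c("mirna", "gene")) {
  kind <- match.arg(kind)
  if (is.character(aliases) && length(aliases) == 1) {
    aliases <- utils::read.delim(aliases, sep = "\t",
                                 colClasses = "character")
  }
  stopifnot(all(c("alias", "canonical") %in% names(aliases)))
  d <- tibble::tibble(alias = as.character(aliases$alias),
                      canonical = as.character(aliases$canonical))
  key <- if (kind == "mirna") tolower(d$alias) else d$alias
  coll <- d[key %in% key[duplicated(key)], ] |>
    dplyr::distinct(.data$alias, .data$canonical)
  if (anyDuplicated(if (kind == "mirna") tolower(coll$alias) else coll$alias)) {
    abort(sprintf("alias '%s' maps to more than one canonical id",
                  coll$alias[1]))
  }
  d <- dplyr::distinct(d)
  self <- tibble::tibble(alias = setdiff(d$canonical, d$alias),
                         canonical = setdiff(d$canonical, d$alias))
  out <- dplyr::bind_rows(d, self)
  tibble::new_tibble(out, class = "alias_map", kind = kind)
}

#' Canonicalize miRNA and gene identifiers of interaction keys
#'
#' Replaces every identifier by its canonical form according to the alias
#' maps; miRNA aliases match case-insensitively, gene ids exactly.
#' Identifiers absent from a map pass through unchanged and are collected
#' in the unmapped report. Canonicalization is idempotent: canonical ids
#' are fixed points of their map.
#'
#' @param keys A data frame with `mirna` and `gene` columns.
#' @param mirna_map,gene_map Optional [alias_map()] objects (or `NULL` to
#'   leave that identifier class untouched).
#' @return `keys` with rewritten identifiers; the attribute `unmapped` is
#'   a tibble (`kind`, `id`) of identifiers not found in the maps.
#' @export
canonicalize <- function(keys, mirna_map = NULL, gene_map = NULL) {
  stopifnot(is.data.frame(keys), all(c("mirna", "gene") %in% names(keys)))
  unmapped <- tibble::tibble(kind = character(), id = character())
  if (!is.null(mirna_map)) {
    lut <- stats::setNames(mirna_map$canonical, tolower(mirna_map$alias))
    hit <- tolower(keys$mirna) %in% names(lut)
    unmapped <- dplyr::bind_rows(unmapped,
      tibble::tibble(kind = "mirna", id = unique(keys$mirna[!hit])))
    keys$mirna <- ifelse(hit, unname(lut[tolower(keys$mirna)]), keys$mirna)
  }
  if (!is.null(gene_map)) {
    lut <- stats::setNames(gene_map$canonical, gene_map$alias)
    hit <- keys$gene %in% names(lut)
    unmapped <- dplyr::bind_rows(unmapped,
      tibble::tibble(kind = "gene", id = unique(keys$gene[!hit])))
    keys$gene <- ifelse(hit, unname(lut[keys$gene]), keys$gene)
  }
  attr(keys, "unmapped") <- unmapped
  keys
}

#' Write an evaluation summary (or any flat record) as JSON
#'
#' @param metrics A one-row data frame or named list of scalars.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(as.list(as.data.frame(metrics)), path,
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}
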