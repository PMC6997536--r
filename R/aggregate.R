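#' Beta order-statistic scores for one row of normalized ranks
#'
#' Under the null hypothesis that a row's normalized ranks are independent
#' uniforms on (0, 1], the k-th smallest of n ranks follows a Beta(k,
#' n-k+1) distribution. The k-th score is the CDF of that distribution
#' evaluated at the k-th order statistic: a per-order-statistic p-value for
#' how surprisingly small the k best ranks are.
#'
#' @param row Numeric vector of normalized ranks in (0, 1] (after max-rank
#'   imputation). Sorted internally.
#' @param n Number of sources; defaults to `length(row)`.
#' @return Numeric vector of length `n`: `pbeta(r_(k), k, n - k + 1)`.
#' @examples
#' beta_scores(c(0.1, 0.2))  # c(1 - 0.9^2, 0.2^2)
#' @export
beta_scores <- function(row, n = length(row)) {
  check_rank_row(row, n)
  r <- sort(row)
  k <- seq_len(n)
  pbeta(r, k, n - k + 1)
}

#' Rho score: Bonferroni-corrected minimum beta order-statistic p-value
#'
#' The rho score of a row is the smallest of its [beta_scores()], corrected
#' for having looked at n order statistics by multiplying by n and capping
#' at 1. Lower is better; under a uniform null the corrected score is
#' super-uniform, so it can be read as a significance level for the
#' consensus ranking of the interaction.
#'
#' @inheritParams beta_scores
#' @return A single corrected score in (0, 1].
#' @examples
#' rra_rho(c(0.1, 0.2))  # min(0.19, 0.04) * 2 = 0.08
#' @export
rra_rho <- function(row, n = length(row)) {
  rho <- min(beta_scores(row, n))
  min(rho * n, 1)
}

#' Stuart joint-probability score for one row of normalized ranks
#'
#' Computes the exact joint null probability that all n order statistics of
#' n independent uniforms are at most the observed values: q = P(R_(1) <=
#' r_(1), ..., R_(n) <= r_(n)). Evaluated by the alternating recursion
#' v_0 = 1, v_k = sum_{i=1..k} (-1)^(i-1) v_{k-i} r_(n-k+1)^i / i!, with
#' q = n! v_n.
#'
#' @param row Numeric vector of normalized ranks in (0, 1], sorted
#'   ascending (an unsorted row is an error).
#' @param n Number of sources; defaults to `length(row)`.
#' @return The joint probability q in (0, 1].
#' @examples
#' stuart_q(c(0.1, 0.2))  # 0.03
#' @export
stuart_q <- function(row, n = length(row)) {
  check_rank_row(row, n)
  if (is.unsorted(row)) abort("`row` must be sorted ascending")
  drop(stuart_q_rows(matrix(row, nrow = 1)))
}

check_rank_row <- function(row, n) {
  if (n < 1) abort("`n` must be at least 1")
  if (length(row) != n) abort("`row` must have length `n`")
  if (!all(is.finite(row)) || any(row <= 0) || any(row > 1)) {
    abort("normalized ranks must lie in (0, 1]")
  }
  invisible(row)
}

# Vectorized Stuart recursion over rows of a matrix sorted ascending
# within each row. n is small (the number of sources), so the O(n^2)
# recursion in vectorized arithmetic is exact and fast.
stuart_q_rows <- function(sorted) {
  n <- ncol(sorted)
  nr <- nrow(sorted)
  v <- vector("list", n + 1)
  v[[1]] <- rep(1, nr)
  for (k in seq_len(n)) {
    r <- sorted[, n - k + 1]
    acc <- rep(0, nr)
    rp <- rep(1, nr)
    fact <- 1
    for (i in seq_len(k)) {
      rp <- rp * r
      fact <- fact * i
      term <- v[[k - i + 1]] * rp / fact
      acc <- if (i %% 2 == 1) acc + term else acc - term
    }
    v[[k + 1]] <- acc
  }
  pmin(pmax(factorial(n) * v[[n + 1]], 0), 1)
}

# Row-wise ascending sort of a numeric matrix, vectorized.
sort_rows <- function(m) {
  o <- order(row(m), m)
  matrix(m[o], nrow = nrow(m), byrow = TRUE)
}

rra_rho_rows <- function(sorted) {
  n <- ncol(sorted)
  pb <- sorted
  for (k in seq_len(n)) pb[, k] <- pbeta(sorted[, k], k, n - k + 1)
  rho <- do.call(pmin, as.data.frame(pb))
  pmin(rho * n, 1)
}

#' Aggregate a rank matrix into a single reranked list
#'
#' Summarizes each interaction's row of normalized relative ranks (missing
#' sources imputed at 1) with the selected aggregation function and reranks
#' all interactions by the resulting score, lower = better. Ties in the
#' aggregated score are broken by the number of sources listing the
#' interaction (more first), then by miRNA and gene identifier, so output
#' order is fully deterministic.
#'
#' @param matrix A `rank_matrix` from [build_rank_matrix()].
#' @param method One of `"mean"` (arithmetic mean of the row), `"median"`,
#'   `"min"`, `"geomean"`, `"stuart"` ([stuart_q()] joint probability), or
#'   `"rra"` (the [rra_rho()] corrected beta order-statistic score;
#'   `"default"` and `"rra_default"` are accepted aliases).
#' @param threshold Optional score cutoff in (0, 1]; when given, only
#'   interactions with score <= threshold are returned (see
#'   [filter_by_threshold()]).
#' @return A tibble of class `aggregation` with columns `mirna`, `gene`,
#'   `score`, `rank`, `n_sources`, and one `rank_<source>` column per
#'   source holding that source's (mid)rank or `NA` when absent.
#' @examples
#' preds <- tibble::tibble(
#'   source = rep(c("a", "b"), each = 2),
#'   mirna = "hsa-miR-16-5p", gene = c("G1", "G2", "G1", "G3"),
#'   score = c(1, 2, 1, 2)
#' )
#' aggregate_ranks(build_rank_matrix(preds), "rra")
#' @export
aggregate_ranks <- function(matrix, method = c("mean", "median", "min",
                                               "geomean", "stuart", "rra",
                                               "default", "rra_default"),
                            threshold = NULL) {
  method <- match.arg(method)
  if (method %in% c("default", "rra_default")) method <- "rra"
  vals <- rank_matrix_values(matrix)
  n <- ncol(vals)

  score <- switch(method,
    mean = rowMeans(vals),
    median = row_medians(vals),
    min = do.call(pmin, as.data.frame(vals)),
    geomean = exp(rowMeans(log(vals))),
    stuart = stuart_q_rows(sort_rows(vals)),
    rra = rra_rho_rows(sort_rows(vals))
  )

  mid <- attr(matrix, "midrank")
  n_sources <- rowSums(!is.na(mid))
  out <- tibble::tibble(
    mirna = matrix$mirna,
    gene = matrix$gene,
    score = score,
    n_sources = as.integer(n_sources)
  )
  rk <- tibble::as_tibble(mid)
  names(rk) <- paste0("rank_", attr(matrix, "sources"))
  out <- dplyr::bind_cols(out, rk) |>
    dplyr::arrange(.data$score, dplyr::desc(.data$n_sources),
                   .data$mirna, .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number(), .after = "score")
  out <- tibble::new_tibble(out, class = "aggregation",
                            method = method)
  if (!is.null(threshold)) out <- filter_by_threshold(out, threshold)
  out
}

row_medians <- function(m) {
  # median of each row without apply(): mean of the two middle order stats
  s <- sort_rows(m)
  n <- ncol(m)
  if (n %% 2 == 1) s[, (n + 1) / 2] else (s[, n / 2] + s[, n / 2 + 1]) / 2
}

#' P-value of a mean of uniform ranks under the Irwin-Hall/Bates null
#'
#' The null probability that the mean of n independent uniform (0, 1]
#' ranks is at most the observed mean. The transform is strictly monotone
#' in the mean, so ranking by this p-value and ranking by the raw mean are
#' identical; it is offered for reporting the mean-aggregation score on a
#' significance-like scale.
#'
#' @param mean_rank Observed mean of the n normalized ranks, in (0, 1].
#' @param n Number of sources.
#' @return `P(mean of n uniforms <= mean_rank)`.
#' @examples
#' bates_p(0.25, 2)  # P(U1 + U2 <= 0.5) = 0.125
#' @export
bates_p <- function(mean_rank, n) {
  stopifnot(n >= 1, all(mean_rank >= 0), all(mean_rank <= 1))
  # the distribution is symmetric about 1/2; evaluating the alternating
  # polynomial only on the lower half keeps the sum numerically stable
  upper <- mean_rank > 0.5
  x <- ifelse(upper, 1 - mean_rank, mean_rank)
  s <- x * n
  out <- numeric(length(s))
  for (k in 0:n) {
    active <- s >= k
    if (!any(active)) break
    out[active] <- out[active] +
      (-1)^k * choose(n, k) * (s[active] - k)^n
  }
  p <- pmin(pmax(out / factorial(n), 0), 1)
  ifelse(upper, 1 - p, p)
}

#' Filter an aggregated list by score threshold
#'
#' Retains interactions whose aggregated score is at or below the cutoff,
#' preserving order. A cutoff of 0.05 is the recommended working threshold
#' for significance-like scores such as the rho score.
#'
#' @param results An `aggregation` tibble (or any data frame with a
#'   `score` column).
#' @param threshold Score cutoff in (0, 1].
#' @return The filtered tibble.
#' @export
filter_by_threshold <- function(results, threshold = 0.05) {
  stopifnot(is.data.frame(results), "score" %in% names(results))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    abort("`threshold` must be a single value in (0, 1]")
  }
  dplyr::filter(results, .data$score <= threshold)
}
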