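#' Build a benchmark set from the interactions common to all methods
#'
#' Keeps exactly the (miRNA, gene) interactions scored by every method,
#' carrying each method's score as a column, and attaches 0/1 validation
#' labels. Comparing tools only on their common predictions is what makes
#' per-method metrics comparable: every method ranks the same universe.
#'
#' @param predictions Long data frame with columns `method` (or `source`),
#'   `mirna`, `gene`, `score`.
#' @param labels Optional data frame of validated pairs with columns
#'   `mirna`, `gene`; interactions present there get label 1.
#' @return A tibble of class `benchmark_set` with columns `mirna`, `gene`,
#'   `label` (if labels were given) and one `score_<method>` column per
#'   method, in deterministic key order. An empty intersection is returned
#'   (with a warning), not an error.
#' @export
intersect_common <- function(predictions, labels = NULL) {
  stopifnot(is.data.frame(predictions))
  if (!"method" %in% names(predictions) && "source" %in% names(predictions)) {
    predictions <- dplyr::rename(predictions, method = "source")
  }
  need <- c("method", "mirna", "gene", "score")
  if (!all(need %in% names(predictions))) {
    abort("`predictions` needs columns method (or source), mirna, gene, score")
  }
  methods <- unique(as.character(predictions$method))
  if (length(methods) < 2) abort("need at least 2 methods to intersect")

  wide <- predictions |>
    dplyr::mutate(method = paste0("score_", .data$method)) |>
    tidyr::pivot_wider(id_cols = c("mirna", "gene"),
                       names_from = "method", values_from = "score") |>
    tidyr::drop_na() |>
    dplyr::arrange(.data$mirna, .data$gene)
  if (nrow(wide) == 0) warn("no interactions are common to all methods")

  if (!is.null(labels)) {
    lab <- dplyr::distinct(labels, .data$mirna, .data$gene) |>
      dplyr::mutate(label = 1L)
    wide <- dplyr::left_join(wide, lab, by = c("mirna", "gene")) |>
      dplyr::mutate(label = dplyr::coalesce(.data$label, 0L))
  }
  tibble::new_tibble(wide, class = "benchmark_set", methods = methods)
}

#' Draw prevalence-matched replicate subsets of a benchmark set
#'
#' Draws `n_replicates` subsets of `size` interactions without replacement,
#' stratified on the validation label so each replicate's count of
#' positives equals `round(size * parent prevalence)` exactly. Replicate i
#' uses the deterministic seed `seed + i`, so a run is reproducible from
#' the single top-level seed.
#'
#' @param parent A `benchmark_set` (or any data frame) with a `label`
#'   column.
#' @param n_replicates Number of replicate subsets; default 10.
#' @param size Number of interactions per replicate; default 50000.
#' @param seed Integer base seed.
#' @return A list of `n_replicates` tibbles, each with attributes
#'   `replicate` and `seed`.
#' @export
subsample_replicates <- function(parent, n_replicates = 10, size = 50000,
                                 seed = 1) {
  stopifnot(is.data.frame(parent), "label" %in% names(parent))
  if (size > nrow(parent)) abort("`size` exceeds the parent set")
  if (n_replicates < 1) abort("`n_replicates` must be at least 1")
  pos <- which(parent$label == 1)
  neg <- which(parent$label == 0)
  n_pos <- round(size * length(pos) / nrow(parent))
  if (n_pos > length(pos) || size - n_pos > length(neg)) {
    abort("stratified draw impossible: a class is too small")
  }
  lapply(seq_len(n_replicates), function(i) {
    set.seed(seed + i)
    idx <- sort(c(sample(pos, n_pos), sample(neg, size - n_pos)))
    out <- parent[idx, ]
    attr(out, "replicate") <- i
    attr(out, "seed") <- seed + i
    out
  })
}

#' Evaluate every method on every replicate
#'
#' Runs [evaluate_ranking()] for each method's score column on each
#' replicate and returns the per-replicate metric table together with the
#' per-method mean and standard deviation of every metric.
#'
#' @param replicates List of benchmark-set tibbles (see
#'   [subsample_replicates()]), each with a `label` column and
#'   `score_<method>` columns.
#' @param methods Character vector of method names; default: all
#'   `score_*` columns found in the first replicate.
#' @inheritParams evaluate_ranking
#' @return A list with `metrics` (one row per replicate x method) and
#'   `summary` (per method and metric: mean, sd, formatted `mean +/- sd`).
#' @export
evaluate_all <- function(replicates, methods = NULL, spec_min = 0.9,
                         fractions = c(0.05, 0.1, 0.2, 1)) {
  stopifnot(is.list(replicates), length(replicates) >= 1)
  score_cols <- grep("^score_", names(replicates[[1]]), value = TRUE)
  if (is.null(methods)) methods <- sub("^score_", "", score_cols)
  metrics <- purrr::map_dfr(seq_along(replicates), function(i) {
    rep_i <- replicates[[i]]
    purrr::map_dfr(methods, function(m) {
      col <- paste0("score_", m)
      if (!col %in% names(rep_i)) {
        abort(sprintf("method '%s' missing from replicate %d", m, i))
      }
      dplyr::bind_cols(
        tibble::tibble(replicate = i, method = m),
        evaluate_ranking(rep_i, score = .data[[col]], label = .data$label,
                         spec_min = spec_min, fractions = fractions)
      )
    })
  })
  summary <- metrics |>
    dplyr::select(-"replicate", -"n", -"prevalence") |>
    tidyr::pivot_longer(-"method", names_to = "metric") |>
    dplyr::group_by(.data$method, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) sd(.data$value) else 0,
                     .groups = "drop") |>
    dplyr::mutate(formatted = sprintf("%.4f ± %.4f",
                                      .data$mean, .data$sd))
  list(metrics = metrics, summary = summary)
}

#' Repeated-measures one-way ANOVA on a replicates x methods table
#'
#' Treats replicates as subjects and methods as the within-subject factor:
#' F = MS_method / MS_(method x replicate), with (k - 1, (k - 1)(n - 1))
#' degrees of freedom. No sphericity correction is applied.
#'
#' @param metric_table A numeric matrix (replicates x methods) or a long
#'   data frame with columns `replicate`, `method`, `value` (complete).
#' @return A one-row tibble: `statistic` (F), `df`, `df_error`, `p.value`,
#'   and `degenerate` (TRUE when the error variance is exactly zero while
#'   methods differ, reported as p = 0).
#' @export
rm_anova <- function(metric_table) {
  m <- as_metric_matrix(metric_table)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) abort("need >= 2 replicates and >= 2 methods")
  gm <- mean(m)
  ss_method <- n * sum((colMeans(m) - gm)^2)
  ss_subj <- k * sum((rowMeans(m) - gm)^2)
  ss_tot <- sum((m - gm)^2)
  ss_err <- max(ss_tot - ss_method - ss_subj, 0)
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_method <- ss_method / df1
  ms_err <- ss_err / df2
  degenerate <- FALSE
  if (ms_err == 0) {
    if (ms_method == 0) {
      f <- 0; p <- 1
    } else {
      f <- Inf; p <- 0; degenerate <- TRUE
    }
  } else {
    f <- ms_method / ms_err
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }
  tibble::tibble(statistic = f, df = df1, df_error = df2, p.value = p,
                 degenerate = degenerate)
}

as_metric_matrix <- function(metric_table) {
  if (is.matrix(metric_table)) {
    if (anyNA(metric_table)) abort("metric table must be complete")
    return(metric_table)
  }
  stopifnot(is.data.frame(metric_table))
  need <- c("replicate", "method", "value")
  if (!all(need %in% names(metric_table))) {
    abort("long metric table needs columns replicate, method, value")
  }
  wide <- tidyr::pivot_wider(metric_table, id_cols = "replicate",
                             names_from = "method", values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  if (anyNA(m)) abort("metric table must be complete")
  m
}

#' Paired two-sided t-test with degenerate-difference handling
#'
#' @param a,b Equal-length numeric vectors (paired by position, length
#'   >= 2).
#' @return A one-row tibble: `estimate` (mean difference), `statistic`,
#'   `df`, `p.value`, and `degenerate`, which is TRUE when the differences
#'   have zero variance (all-zero differences are reported as an exact tie
#'   with t = 0; constant nonzero differences leave t and p undefined).
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    abort("`a` and `b` must have equal length >= 2")
  }
  d <- a - b
  n <- length(d)
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(estimate = 0, statistic = 0, df = n - 1,
                            p.value = 1, degenerate = TRUE))
    }
    return(tibble::tibble(estimate = mean(d), statistic = NA_real_,
                          df = n - 1, p.value = NA_real_, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(estimate = unname(ht$estimate),
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p.value = ht$p.value, degenerate = FALSE)
}

#' Dunnett-style many-to-one comparisons by seeded Monte-Carlo
#'
#' Compares every non-control method to the control with paired t
#' statistics and adjusts for multiplicity against the null distribution
#' of the maximum absolute t over all contrasts. That null is estimated by
#' Monte-Carlo: replicate-level difference vectors are resampled from a
#' multivariate normal with the estimated within-subject covariance of the
#' observed differences, and the paired t statistics recomputed per draw.
#' This respects the correlation structure that repeated measures induce
#' instead of assuming equicorrelated contrasts. With a single contrast
#' the exact paired t p-value is returned unadjusted.
#'
#' @inheritParams rm_anova
#' @param control Name of the control method (a column of the table).
#' @param n_draws Monte-Carlo draws for the max-|t| null; default 1e5.
#' @param seed Seed for the draws; default 1.
#' @return A tibble with one row per non-control method: `estimate` (mean
#'   difference vs control), `statistic`, `p.value` (unadjusted paired t),
#'   `adj.p.value` (Monte-Carlo max-|t| adjusted, never below the
#'   unadjusted value), and `significant` at the 0.05 level.
#' @export
dunnett_posthoc <- function(metric_table, control, n_draws = 1e5, seed = 1) {
  m <- as_metric_matrix(metric_table)
  if (!control %in% colnames(m)) abort("`control` not found in the table")
  others <- setdiff(colnames(m), control)
  if (length(others) == 0) abort("need at least one non-control method")
  n <- nrow(m)
  D <- m[, others, drop = FALSE] - m[, control]
  mu <- colMeans(D)
  sdev <- apply(D, 2, sd)
  tstat <- ifelse(sdev == 0, ifelse(mu == 0, 0, Inf),
                  mu / (sdev / sqrt(n)))
  p_raw <- vapply(others, function(j) {
    paired_ttest(m[, j], m[, control])$p.value
  }, numeric(1))

  k <- length(others)
  if (k == 1) {
    adj <- p_raw
  } else if (all(sdev == 0)) {
    adj <- ifelse(mu == 0, 1, 0)
  } else {
    sig <- cov(D)
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
    Z <- MASS::mvrnorm(n * n_draws, mu = rep(0, k), Sigma = sig)
    g <- rep(seq_len(n_draws), each = n)
    means <- rowsum(Z, g) / n
    ssq <- rowsum(Z^2, g)
    vars <- (ssq - n * means^2) / (n - 1)
    tnull <- abs(means / sqrt(vars / n))
    tnull[!is.finite(tnull)] <- 0
    maxt <- do.call(pmax, as.data.frame(tnull))
    adj <- vapply(abs(tstat), function(t0) {
      (1 + sum(maxt >= t0)) / (n_draws + 1)
    }, numeric(1))
    adj <- pmax(adj, p_raw, na.rm = TRUE)
  }
  tibble::tibble(method = others, estimate = mu, statistic = unname(tstat),
                 p.value = unname(p_raw), adj.p.value = unname(pmin(adj, 1)),
                 significant = unname(pmin(adj, 1)) < 0.05)
}

get_rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' Compare methods across replicates with ANOVA and a Dunnett post-test
#'
#' The full comparison protocol on one family of replicates: evaluate
#' every method on every replicate, then for each requested metric run the
#' repeated-measures ANOVA across methods and, when more than two methods
#' are present, the Monte-Carlo Dunnett post-test of every method against
#' the control (for exactly two methods, the paired t-test is used). A
#' method is flagged significant when its adjusted p-value is below 0.05.
#'
#' @inheritParams evaluate_all
#' @param control Name of the reference method for the post-test.
#' @param compare_metrics Metrics to test; default `"roc_auc"` and
#'   `"pr_auc"`.
#' @param n_draws,seed Passed to [dunnett_posthoc()].
#' @return An object of class `method_comparison`: a list with `metrics`
#'   (replicate x method table), `summary` (mean +/- sd per method and
#'   metric), `anova` (one row per tested metric) and `posthoc` (adjusted
#'   p-values vs the control per metric), plus the control name.
#' @export
compare_methods <- function(replicates, control, methods = NULL,
                            compare_metrics = c("roc_auc", "pr_auc"),
                            spec_min = 0.9,
                            fractions = c(0.05, 0.1, 0.2, 1),
                            n_draws = 1e5, seed = 1) {
  ev <- evaluate_all(replicates, methods = methods, spec_min = spec_min,
                     fractions = fractions)
  if (!control %in% ev$metrics$method) abort("`control` was not evaluated")
  anova_tbl <- purrr::map_dfr(compare_metrics, function(met) {
    tab <- metric_long(ev$metrics, met)
    dplyr::bind_cols(tibble::tibble(metric = met), rm_anova(tab))
  })
  posthoc <- purrr::map_dfr(compare_metrics, function(met) {
    tab <- metric_long(ev$metrics, met)
    dplyr::bind_cols(tibble::tibble(metric = met),
                     dunnett_posthoc(tab, control = control,
                                     n_draws = n_draws, seed = seed))
  })
  structure(list(metrics = ev$metrics, summary = ev$summary,
                 anova = anova_tbl, posthoc = posthoc, control = control),
            class = "method_comparison")
}

metric_long <- function(metrics, metric) {
  tibble::tibble(replicate = metrics$replicate, method = metrics$method,
                 value = metrics[[metric]])
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> %d methods x %d replicates, control = %s\n",
              length(unique(x$metrics$method)),
              max(x$metrics$replicate), x$control))
  cat("\nANOVA (repeated measures):\n")
  print(x$anova)
  cat("\nPost-test vs control:\n")
  print(x$posthoc)
  invisible(x)
}
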