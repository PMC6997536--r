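test_that("beta order-statistic scores match the closed-form extremes", {
  expect_equal(beta_scores(0.05), 0.05)            # Beta(1,1) is uniform
  # n = 2 closed forms: P(min <= x) = 1 - (1-x)^2, P(max <= x) = x^2
  expect_equal(beta_scores(c(0.1, 0.2)), c(1 - 0.9^2, 0.2^2))
  expect_equal(beta_scores(rep(1, 5)), rep(1, 5))
  expect_error(beta_scores(c(0, 0.5)), "\\(0, 1\\]")
  expect_error(beta_scores(c(0.5, 1.5)), "\\(0, 1\\]")
})

test_that("rho score is the Bonferroni-corrected minimum beta score", {
  expect_equal(rra_rho(c(0.1, 0.2)), 0.04 * 2)
  expect_equal(rra_rho(0.05), 0.05)
  expect_lte(rra_rho(c(0.9, 0.95, 1)), 1)
  expect_equal(rra_rho(rep(1, 4)), 1)
})

test_that("Stuart recursion agrees with direct integration at small n", {
  expect_equal(stuart_q(0.3), 0.3)
  # n = 2 by integration: P(both <= r2) - P(both in (r1, r2])
  expect_equal(stuart_q(c(0.1, 0.2)), 0.2^2 - (0.2 - 0.1)^2)
  expect_equal(stuart_q(c(0.1, 0.2)), 0.03)
  expect_equal(stuart_q(rep(1, 4)), 1)
  # n = 3 oracle: trivariate integral by nested closed form
  r <- c(0.2, 0.5, 0.9)
  oracle <- integrate(Vectorize(function(x1) {
    integrate(Vectorize(function(x2) {
      max(r[3] - x2, 0) * 6
    }), lower = x1, upper = r[2])$value
  }), lower = 0, upper = r[1])$value
  expect_equal(stuart_q(r), oracle, tolerance = 1e-8)
  expect_error(stuart_q(c(0.5, 0.2)), "sorted")
})

test_that("aggregation methods reduce rows as defined and rerank by score", {
  rm <- build_rank_matrix(toy_predictions())
  vals <- as.matrix(rm[, c("a", "b", "c")])
  expect_equal(aggregate_ranks(rm, "mean")$score |> sort(),
               sort(rowMeans(vals)))
  med <- aggregate_ranks(rm, "median")
  expect_equal(sort(med$score), sort(apply(vals, 1, median)))
  expect_equal(sort(aggregate_ranks(rm, "min")$score),
               sort(apply(vals, 1, min)))
  expect_equal(sort(aggregate_ranks(rm, "geomean")$score),
               sort(apply(vals, 1, function(r) prod(r)^(1 / 3))))
  st <- aggregate_ranks(rm, "stuart")
  expect_equal(sort(st$score),
               sort(apply(vals, 1, function(r) stuart_q(sort(r)))))
  rra <- aggregate_ranks(rm, "rra")
  expect_equal(sort(rra$score),
               sort(apply(vals, 1, function(r) rra_rho(sort(r)))))
  # rank is a permutation of 1..N consistent with ascending score
  for (res in list(med, st, rra)) {
    expect_equal(sort(res$rank), seq_len(nrow(res)))
    expect_false(is.unsorted(res$score))
  }
})

test_that("imputation feeds 1.0 rows into every method", {
  preds <- tibble::tibble(
    source = c("a", "a", "b", "b", "c", "c"),
    mirna = "m",
    gene = c("G1", "G2", "G1", "G3", "G1", "G4"),
    score = rep(c(1, 2), 3)
  )
  agg <- aggregate_ranks(build_rank_matrix(preds), "mean")
  g2 <- agg[agg$gene == "G2", ]
  # G2 listed only by a at normalized rank 1 -> row (1, 1, 1)
  expect_equal(g2$score, 1)
  expect_equal(g2$n_sources, 1L)
  expect_equal(g2$rank_a, 2)
  expect_true(is.na(g2$rank_b) && is.na(g2$rank_c))
})

test_that("source order never changes aggregated scores", {
  sim <- simulate_sources(300, n_sources = 4, coverage = 0.7, seed = 11)
  shuffled <- dplyr::arrange(sim$predictions, dplyr::desc(source), gene)
  for (method in c("mean", "median", "min", "geomean", "stuart", "rra")) {
    a <- aggregate_ranks(build_rank_matrix(sim$predictions, sim$directions),
                         method)
    b <- aggregate_ranks(build_rank_matrix(shuffled, sim$directions), method)
    merged <- dplyr::inner_join(a, b, by = c("mirna", "gene"))
    expect_equal(merged$score.x, merged$score.y, tolerance = 1e-12)
  }
})

test_that("improving one source rank never worsens the aggregated score", {
  base <- tibble::tibble(
    source = rep(c("a", "b"), each = 5),
    mirna = "m", gene = rep(paste0("G", 1:5), 2),
    score = c(1, 2, 3, 4, 5,  5, 4, 3, 2, 1)
  )
  for (method in c("mean", "median", "min", "geomean", "stuart", "rra")) {
    before <- aggregate_ranks(build_rank_matrix(base), method)
    improved <- base
    improved$score[improved$source == "a" & improved$gene == "G3"] <- 0.5
    after <- aggregate_ranks(build_rank_matrix(improved), method)
    expect_lte(after$score[after$gene == "G3"],
               before$score[before$gene == "G3"])
  }
})

test_that("a unanimous top interaction gets the best score of every method", {
  preds <- tibble::tibble(
    source = rep(c("a", "b", "c"), each = 4),
    mirna = "m", gene = rep(paste0("G", 1:4), 3),
    score = c(1, 2, 3, 4,  1, 4, 2, 3,  1, 3, 4, 2)
  )
  rm <- build_rank_matrix(preds)
  for (method in c("mean", "median", "min", "geomean", "stuart", "rra")) {
    agg <- aggregate_ranks(rm, method)
    expect_equal(agg$gene[agg$rank == 1], "G1")
    expect_equal(agg$score[agg$rank == 1], min(agg$score))
  }
})

test_that("Bates mean-rank p-values match the Irwin-Hall closed form", {
  expect_equal(bates_p(0.25, 2), 0.125)    # P(U1 + U2 <= 0.5) = 0.5^2/2
  expect_equal(bates_p(0.5, 2), 0.5)       # symmetry point
  expect_equal(bates_p(0.75, 2), 0.875)
  expect_equal(bates_p(1, 4), 1)
  # Monte-Carlo spot check at n = 3
  set.seed(14)
  u <- matrix(runif(3e5), ncol = 3)
  p_hat <- mean(rowMeans(u) <= 0.4)
  expect_lt(abs(bates_p(0.4, 3) - p_hat),
            3 * sqrt(p_hat * (1 - p_hat) / 1e5))
})

test_that("score threshold filtering keeps only significant interactions", {
  res <- tibble::tibble(mirna = "m", gene = paste0("G", 1:3),
                        score = c(0.01, 0.05, 0.051))
  expect_equal(filter_by_threshold(res, 0.05)$gene, c("G1", "G2"))
  expect_equal(filter_by_threshold(res, 1), res)
  expect_equal(nrow(filter_by_threshold(res[0, ], 0.05)), 0)
  expect_error(filter_by_threshold(res, 0), "\\(0, 1\\]")
})
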