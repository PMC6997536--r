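test_that("intersect_common keeps exactly the shared interactions", {
  preds <- tibble::tibble(
    method = rep(c("x", "y"), each = 3),
    mirna = "m",
    gene = c("A", "B", "C",  "B", "C", "D"),
    score = c(1, 2, 3, 4, 5, 6)
  )
  bs <- intersect_common(preds)
  expect_equal(bs$gene, c("B", "C"))
  expect_equal(bs$score_x, c(2, 3))
  expect_equal(bs$score_y, c(4, 5))

  # identical lists intersect to themselves
  same <- dplyr::mutate(preds, method = rep(c("x", "y"), each = 3),
                        gene = rep(c("A", "B", "C"), 2))
  expect_equal(nrow(intersect_common(same)), 3)

  # single shared key across three lists, with labels attached
  tri <- tibble::tibble(
    method = rep(c("x", "y", "z"), each = 2),
    mirna = "m",
    gene = c("A", "K", "B", "K", "C", "K"),
    score = 1:6
  )
  one <- intersect_common(tri, labels = tibble::tibble(mirna = "m",
                                                       gene = "K"))
  expect_equal(one$gene, "K")
  expect_equal(one$label, 1L)
  expect_equal(unlist(one[, c("score_x", "score_y", "score_z")],
                      use.names = FALSE), c(2, 4, 6))

  empty <- tibble::tibble(method = rep(c("x", "y"), each = 1),
                          mirna = "m", gene = c("A", "B"), score = 1:2)
  expect_warning(res <- intersect_common(empty), "common")
  expect_equal(nrow(res), 0)
})

test_that("replicate subsampling is stratified and seed-deterministic", {
  parent <- tibble::tibble(
    mirna = "m", gene = as.character(1:2000),
    score_x = runif(2000),
    label = c(rep(1L, 100), rep(0L, 1900))
  )
  reps <- subsample_replicates(parent, n_replicates = 5, size = 400,
                               seed = 3)
  expect_length(reps, 5)
  for (r in reps) {
    expect_equal(nrow(r), 400)
    expect_equal(sum(r$label), 20)   # 5% of 400, matching the parent
  }
  reps2 <- subsample_replicates(parent, n_replicates = 5, size = 400,
                                seed = 3)
  expect_identical(lapply(reps, as.data.frame), lapply(reps2, as.data.frame))
  # exhaustive draw returns the parent itself
  full <- subsample_replicates(parent, n_replicates = 2, size = 2000,
                               seed = 1)
  expect_equal(nrow(full[[1]]), 2000)
  expect_setequal(full[[1]]$gene, parent$gene)
  expect_error(subsample_replicates(parent, size = 3000), "exceeds")
})

test_that("evaluate_all reports per-replicate metrics and mean/sd", {
  parent <- tibble::tibble(
    mirna = "m", gene = as.character(1:500),
    label = rep(c(1L, 0L, 0L, 0L, 0L), 100)
  )
  set.seed(5)
  parent$score_good <- ifelse(parent$label == 1, runif(500, 0, 0.3),
                              runif(500))
  parent$score_bad <- runif(500)
  reps <- subsample_replicates(parent, n_replicates = 4, size = 200,
                               seed = 2)
  ev <- evaluate_all(reps)
  expect_equal(nrow(ev$metrics), 8)
  auc <- dplyr::filter(ev$summary, metric == "roc_auc")
  expect_gt(auc$mean[auc$method == "good"], auc$mean[auc$method == "bad"])
  expect_match(auc$formatted[1], "^0\\.\\d{4} ± 0\\.\\d{4}$")

  # identical replicates give zero sd
  same <- evaluate_all(list(parent, parent))
  expect_equal(dplyr::filter(same$summary, metric == "roc_auc")$sd, c(0, 0))

  expect_error(evaluate_all(reps, methods = "missing"), "missing")
})

test_that("repeated-measures ANOVA matches the aov() decomposition", {
  # textbook-style 4 subjects x 3 conditions within-subject table
  m <- matrix(c(45, 50, 55,
                42, 42, 45,
                36, 41, 43,
                39, 35, 40), nrow = 4, byrow = TRUE,
              dimnames = list(NULL, c("m1", "m2", "m3")))
  res <- rm_anova(m)
  d <- data.frame(value = as.vector(m),
                  method = factor(rep(colnames(m), each = 4)),
                  subj = factor(rep(1:4, 3)))
  fit <- stats::aov(value ~ method + subj, data = d)
  tab <- summary(fit)[[1]]
  row <- which(trimws(rownames(tab)) == "method")
  expect_equal(res$statistic, tab[row, "F value"],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(res$p.value, tab[row, "Pr(>F)"],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(res$df, 2)
  expect_equal(res$df_error, 6)

  # no treatment effect -> F = 0, p = 1
  flat <- matrix(rep(c(1, 2, 3), each = 3), nrow = 3)
  colnames(flat) <- c("a", "b", "c")
  expect_equal(rm_anova(t(flat))$p.value, 1)

  # two methods: F equals the squared paired t statistic
  set.seed(8)
  two <- cbind(a = rnorm(6), b = rnorm(6))
  ra <- rm_anova(two)
  tt <- paired_ttest(two[, "a"], two[, "b"])
  expect_equal(ra$statistic, tt$statistic^2, tolerance = 1e-10)
  expect_equal(ra$p.value, tt$p.value, tolerance = 1e-10)

  # invariance to adding a constant and to relabeling replicates
  expect_equal(rm_anova(two + 5)$statistic, ra$statistic)
  expect_equal(rm_anova(two[c(3, 1, 6, 2, 5, 4), ])$statistic, ra$statistic)
})

test_that("paired t-test matches hand computation and flags degeneracy", {
  r <- paired_ttest(c(1, 2), c(0.5, 0.5))
  expect_equal(r$statistic, 2)       # diffs (0.5, 1.5): mean 1, se 0.5
  expect_equal(r$df, 1)
  expect_equal(paired_ttest(1:4, 1:4)$p.value, 1)
  expect_true(paired_ttest(1:4, 1:4)$degenerate)
  const <- paired_ttest(2:5, 1:4)    # constant nonzero differences
  expect_true(const$degenerate)
  expect_true(is.na(const$p.value))
})

test_that("Dunnett adjustment respects its exactness and ordering bounds", {
  set.seed(21)
  m <- cbind(ctrl = rnorm(8), a = rnorm(8, 0.5), b = rnorm(8))
  # adjusted p is never below the unadjusted paired-t p
  res <- dunnett_posthoc(m, "ctrl", n_draws = 2e4, seed = 1)
  expect_true(all(res$adj.p.value >= res$p.value - 1e-12))

  # two methods total: single contrast, no multiplicity correction
  two <- m[, c("ctrl", "a")]
  r2 <- dunnett_posthoc(two, "ctrl")
  expect_equal(r2$adj.p.value, paired_ttest(m[, "a"], m[, "ctrl"])$p.value)

  # identical columns: every adjusted p is 1
  same <- cbind(ctrl = 1:6, a = 1:6, b = 1:6) * 1.0
  expect_equal(dunnett_posthoc(same, "ctrl")$adj.p.value, c(1, 1))

  expect_error(dunnett_posthoc(m, "nope"), "control")
})

test_that("Dunnett familywise error is near nominal under the global null", {
  set.seed(33)
  hits <- 0
  n_runs <- 300
  for (i in 1:n_runs) {
    m <- matrix(rnorm(10 * 3), ncol = 3,
                dimnames = list(NULL, c("ctrl", "a", "b")))
    res <- dunnett_posthoc(m, "ctrl", n_draws = 3000, seed = i)
    hits <- hits + any(res$adj.p.value < 0.05)
  }
  fwer <- hits / n_runs
  # 3 SE binomial band around 0.05
  expect_lt(abs(fwer - 0.05), 3 * sqrt(0.05 * 0.95 / n_runs) + 0.01)
})

test_that("compare_methods flags a dominating method against the control", {
  parent <- tibble::tibble(mirna = "m", gene = as.character(1:4000),
                           label = rep(c(1L, rep(0L, 19)), 200))
  set.seed(12)
  parent$score_strong <- rnorm(4000) - 1.5 * parent$label
  parent$score_weak <- rnorm(4000) - 0.3 * parent$label
  reps <- subsample_replicates(parent, n_replicates = 6, size = 1500,
                               seed = 4)
  cmp <- compare_methods(reps, control = "weak",
                         compare_metrics = "roc_auc",
                         n_draws = 2e4, seed = 9)
  expect_s3_class(cmp, "method_comparison")
  expect_lt(cmp$anova$p.value, 0.05)
  expect_true(all(cmp$posthoc$significant))
  expect_gt(cmp$posthoc$estimate, 0)   # strong beats weak on AUC

  g <- glance(cmp)
  expect_equal(g$metric, "roc_auc")
  expect_equal(g$min_adj_p, min(cmp$posthoc$adj.p.value))
  expect_equal(tidy(cmp), cmp$metrics)
  expect_s3_class(autoplot(cmp), "ggplot")
  expect_output(print(cmp), "method_comparison")
})
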