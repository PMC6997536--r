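# Small deterministic fixtures shared across test files.

toy_predictions <- function() {
  tibble::tibble(
    source = rep(c("a", "b", "c"), each = 4),
    mirna = "hsa-miR-16-5p",
    gene = rep(c("G1", "G2", "G3", "G4"), 3),
    score = c(1, 2, 3, 4,  2, 1, 4, 3,  4, 3, 2, 1)
  )
}

# End-to-end pipeline on simulated data: returns a labeled aggregation.
sim_pipeline <- function(n = 1000, method = "mean", seed = 1, ...) {
  sim <- simulate_sources(n, seed = seed, ...)
  m <- build_rank_matrix(sim$predictions, sim$directions)
  agg <- aggregate_ranks(m, method)
  label_interactions(agg, dplyr::filter(sim$truth, label == 1))
}

# Brute-force Mann-Whitney AUC with half credit for ties (lower = better).
mw_auc <- function(score, label) {
  sp <- score[label == 1]
  sn <- score[label == 0]
  cmp <- outer(sp, sn, function(p, q) (p < q) + 0.5 * (p == q))
  mean(cmp)
}
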