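#' Simulate divergent multi-source prediction lists with known truth
#'
#' Generates a universe of miRNA::gene interactions, marks an exact
#' fraction of them as validated, and emits one prediction list per
#' source. Each source scores interaction i with a latent variable
#' `signal_j * label_i + noise`, so `signal_j` tunes that source's ROC
#' performance (0 = uninformative, about 0.76 AUC at signal 1 with unit
#' Gaussian noise). A source lists only its top `coverage_j` fraction of
#' the universe, chosen independently of the label by default so
#' missingness carries no information; `coverage_bias > 1` makes validated
#' interactions more likely to be listed, to probe how max-rank imputation
#' behaves under informative missingness.
#'
#' @param n_interactions Size of the interaction universe.
#' @param n_sources Number of sources; default 4.
#' @param prevalence Fraction of validated interactions in (0, 1); default
#'   0.05. The count of positives is exactly
#'   `round(prevalence * n_interactions)`.
#' @param coverage Per-source fraction of the universe listed, in (0, 1];
#'   recycled to `n_sources`. Default 1.
#' @param signal Per-source effect size (>= 0) separating validated from
#'   unvalidated latent scores, in units of the noise standard deviation;
#'   recycled. Default 1.
#' @param noise_model `"gaussian"` (additive unit-normal noise on the
#'   latent score, the default) or `"rank_jitter"` (Gaussian perturbation
#'   of the normalized true rank, giving heavier rank-space noise).
#' @param coverage_bias Relative odds that a validated interaction is
#'   listed, versus an unvalidated one; default 1 (uninformative).
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return A list of class `sim_result`: `predictions` (long tibble:
#'   source, mirna, gene, score with higher = better), `directions` (named
#'   vector, all `"higher"`), `truth` (tibble: mirna, gene, label), and
#'   `config` (the arguments).
#' @examples
#' sim <- simulate_sources(200, n_sources = 3, seed = 1)
#' head(sim$predictions)
#' @export
simulate_sources <- function(n_interactions, n_sources = 4,
                             prevalence = 0.05, coverage = 1, signal = 1,
                             noise_model = c("gaussian", "rank_jitter"),
                             coverage_bias = 1, seed = 1) {
  noise_model <- match.arg(noise_model)
  if (n_interactions < 2 || n_sources < 1) abort("degenerate simulation size")
  if (prevalence <= 0 || prevalence >= 1) {
    abort("`prevalence` must be in (0, 1)")
  }
  n_pos <- round(prevalence * n_interactions)
  if (n_pos < 1) abort("`prevalence` too small: no validated interaction")
  coverage <- rep_len(coverage, n_sources)
  signal <- rep_len(signal, n_sources)
  if (any(coverage <= 0 | coverage > 1)) abort("`coverage` must be in (0, 1]")
  if (any(signal < 0)) abort("`signal` must be >= 0")

  set.seed(seed)
  n <- n_interactions
  n_mirna <- max(2, round(n / 2000))
  mirna <- sprintf("hsa-miR-%03d-5p", sample.int(n_mirna, n, replace = TRUE))
  gene <- sprintf("G%06d", seq_len(n))
  label <- integer(n)
  label[sample.int(n, n_pos)] <- 1L

  src_names <- sprintf("source%d", seq_len(n_sources))
  preds <- purrr::map_dfr(seq_len(n_sources), function(j) {
    score <- switch(noise_model,
      gaussian = signal[j] * label + rnorm(n),
      rank_jitter = {
        latent <- signal[j] * label + rnorm(n)
        true_r <- rank(-latent) / n
        -(true_r + rnorm(n, sd = 0.1))   # higher = better
      }
    )
    m_j <- round(coverage[j] * n)
    keep <- if (m_j < n) {
      w <- ifelse(label == 1, coverage_bias, 1)
      sort(sample.int(n, m_j, prob = w))
    } else seq_len(n)
    tibble::tibble(source = src_names[j], mirna = mirna[keep],
                   gene = gene[keep], score = score[keep])
  })

  structure(
    list(predictions = preds,
         directions = stats::setNames(rep("higher", n_sources), src_names),
         truth = tibble::tibble(mirna = mirna, gene = gene, label = label),
         config = list(n_interactions = n, n_sources = n_sources,
                       prevalence = prevalence, coverage = coverage,
                       signal = signal, noise_model = noise_model,
                       coverage_bias = coverage_bias, seed = seed)),
    class = "sim_result"
  )
}

sim_profiles <- list(
  tiny = list(n_interactions = 100, n_sources = 4, prevalence = 0.05,
              coverage = 0.8, signal = 1.5),
  bench = list(n_interactions = 50000, n_sources = 4, prevalence = 0.05,
               coverage = 1, signal = 1),
  paper_scale = list(n_interactions = 1000000, n_sources = 4,
                     prevalence = 0.05, coverage = 1, signal = 1)
)

#' Write a named simulation profile to disk as fixture files
#'
#' Materializes one of the packaged simulation profiles as the plain-text
#' files the aggregation pipeline consumes: one prediction TSV per source,
#' a validated-pair TSV, a JSON sidecar declaring each source's file and
#' sort direction, and (for the `tiny` profile) a small GMT pathway file
#' built over the simulated genes. Files are byte-identical across runs
#' for a fixed seed. Profiles: `tiny` (n = 100, partial coverage, for
#' examples and regression tests), `bench` (n = 50,000, full coverage,
#' 5% prevalence, mirroring the replicate protocol), `paper_scale`
#' (n = 1,000,000, same structure at the scale of the published
#' aggregation comparison).
#'
#' @param profile One of `"tiny"`, `"bench"`, `"paper_scale"`.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; default 7.
#' @return Invisibly, the named character vector of files written.
#' @export
make_fixture <- function(profile = c("tiny", "bench", "paper_scale"),
                         dir, seed = 7) {
  profile <- match.arg(profile)
  cfg <- sim_profiles[[profile]]
  sim <- do.call(simulate_sources, c(cfg, list(seed = seed)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  files <- c()
  srcs <- names(sim$directions)
  for (s in srcs) {
    path <- file.path(dir, paste0(s, ".tsv"))
    d <- dplyr::filter(sim$predictions, .data$source == s)
    writeLines(c("mirna\tgene\tscore",
                 sprintf("%s\t%s\t%.6f", d$mirna, d$gene, d$score)), path)
    files[s] <- path
  }
  lab_path <- file.path(dir, "labels.tsv")
  lab <- dplyr::filter(sim$truth, .data$label == 1)
  writeLines(c("mirna\tgene", sprintf("%s\t%s", lab$mirna, lab$gene)),
             lab_path)
  files["labels"] <- lab_path

  cfg_path <- file.path(dir, "sources.json")
  jsonlite::write_json(
    list(profile = profile, seed = seed,
         sources = purrr::map(srcs, function(s) {
           list(name = s, file = basename(files[[s]]),
                direction = unname(sim$directions[[s]]))
         })),
    cfg_path, auto_unbox = TRUE, pretty = TRUE)
  files["config"] <- cfg_path

  if (profile == "tiny") {
    gmt_path <- file.path(dir, "pathways.gmt")
    g <- sim$truth$gene
    sets <- list(PW1 = g[seq(1, length(g), by = 3)],
                 PW2 = g[seq(2, length(g), by = 5)],
                 PW3 = g[seq(1, 20)])
    writeLines(vapply(names(sets), function(id) {
      paste(c(id, paste0("synthetic pathway ", id), sets[[id]]),
            collapse = "\t")
    }, character(1)), gmt_path)
    files["pathways"] <- gmt_path
  }
  invisible(files)
}
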