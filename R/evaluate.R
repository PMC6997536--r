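#' ROC curve, AUC, and high-specificity summaries for a scored ranking
#'
#' Sweeps the score thresholds of a labeled ranking (lower score = better
#' prediction) and returns the ROC curve with its trapezoidal AUC, the raw
#' partial AUC over the high-specificity band, and the sensitivity at the
#' specificity cutoff. Tied scores are grouped into a single threshold
#' step, so the AUC equals the Mann-Whitney probability that a random
#' positive scores better than a random negative, with half credit for
#' ties.
#'
#' @param data A data frame with a numeric score column and a 0/1 label
#'   column (1 = validated interaction).
#' @param score,label Column names (tidy-eval) holding scores and labels;
#'   default `score` and `label`.
#' @param spec_min Lower bound of the high-specificity band for the
#'   partial AUC; default 0.9.
#' @return An object of class `roc_curve`: a list with `points` (a tibble
#'   of specificity/sensitivity from (1, 0) to (0, 1)), `auc`, `pauc`
#'   (raw area over specificity in \[spec_min, 1\], at most `1 - spec_min`),
#'   `sens_at_spec_min`, `spec_min`, and the class counts.
#' @examples
#' d <- tibble::tibble(score = c(.1, .2, .3, .4), label = c(1, 1, 0, 0))
#' roc_curve(d)$auc
#' @export
roc_curve <- function(data, score = score, label = label, spec_min = 0.9) {
  s <- eval_tidy(enquo(score), data)
  l <- check_labels(eval_tidy(enquo(label), data), s)
  P <- sum(l == 1)
  N <- sum(l == 0)
  if (P == 0 || N == 0) {
    abort("ROC needs at least one positive and one negative")
  }
  o <- order(s)
  s <- s[o]; l <- l[o]
  ends <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[ends]
  fp <- ends - tp
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  pts <- tibble::tibble(specificity = 1 - fpr, sensitivity = tpr)
  structure(
    list(points = pts,
         auc = auc,
         pauc = partial_auc_points(pts, spec_min),
         sens_at_spec_min = sens_at_spec(pts, spec_min),
         spec_min = spec_min,
         n_pos = P, n_neg = N),
    class = "roc_curve"
  )
}

check_labels <- function(l, s) {
  if (length(l) != length(s)) abort("score and label lengths differ")
  if (!all(l %in% c(0, 1))) abort("labels must be 0 or 1")
  if (!all(is.finite(s))) abort("scores must be finite")
  as.integer(l)
}

#' Raw partial AUC of a ROC curve over a high-specificity band
#'
#' Trapezoidal area of sensitivity over specificity restricted to
#' \[spec_min, 1\], with linear interpolation where a curve segment crosses
#' the band boundary. The value is unstandardized: it lies in
#' \[0, 1 - spec_min\] (0.1 for the default 90% band). Set
#' `standardize = TRUE` for the McClish transform onto \[0.5, 1\].
#'
#' @param curve A `roc_curve` object.
#' @param spec_min Lower bound of the specificity band; default 0.9.
#' @param standardize Report the McClish-standardized value instead of the
#'   raw area; default `FALSE`.
#' @return The partial area.
#' @export
partial_auc <- function(curve, spec_min = 0.9, standardize = FALSE) {
  stopifnot(inherits(curve, "roc_curve"))
  a <- partial_auc_points(curve$points, spec_min)
  if (standardize) {
    amax <- 1 - spec_min
    amin <- amax^2 / 2                  # chance area over the band
    a <- 0.5 * (1 + (a - amin) / (amax - amin))
  }
  a
}

partial_auc_points <- function(pts, spec_min) {
  if (spec_min < 0 || spec_min >= 1) abort("`spec_min` must be in [0, 1)")
  sp <- pts$specificity
  se <- pts$sensitivity
  area <- 0
  for (i in seq_len(length(sp) - 1)) {
    a <- sp[i]; b <- sp[i + 1]          # a >= b, moving away from spec 1
    ya <- se[i]; yb <- se[i + 1]
    if (a <= spec_min) break
    if (b < spec_min) {                  # clip segment at the boundary
      yb <- ya + (yb - ya) * (a - spec_min) / (a - b)
      b <- spec_min
    }
    area <- area + (a - b) * (ya + yb) / 2
  }
  area
}

sens_at_spec <- function(pts, at) {
  sp <- pts$specificity
  se <- pts$sensitivity
  exact <- which(sp == at)
  if (length(exact) > 0) return(max(se[exact]))
  i <- which(sp > at)
  i <- i[length(i)]                      # last point with specificity > at
  if (i == length(sp)) return(se[i])
  (se[i] + (se[i + 1] - se[i]) * (sp[i] - at) / (sp[i] - sp[i + 1]))
}

#' Precision-recall curve, average precision, and cumulative F-score
#'
#' Walks down the ranking (ascending score) computing precision TP(i)/i and
#' recall TP(i)/P at each cutoff. The PR area is the average-precision
#' summation, `sum(precision * delta recall)` over threshold steps (tied
#' scores grouped), with no interpolation between PR points. The cumulative
#' F-score F(i) = 2PR/(P+R) is computed at every rank cutoff, together with
#' its value at requested top fractions of the list and its mean over all
#' cutoffs.
#'
#' @inheritParams roc_curve
#' @param fractions Top fractions of the list at which to report F; default
#'   `c(0.05, 0.1, 0.2, 1)`. The cutoff for fraction x is `round(x * N)`,
#'   at least 1.
#' @return An object of class `pr_curve`: a list with `points` (recall,
#'   precision at each threshold step), `pr_auc`, `f_curve` (a tibble of
#'   cutoff, fraction, precision, recall, f), `f_at_fraction` (named vector),
#'   `mean_f`, and `prevalence`.
#' @examples
#' d <- tibble::tibble(score = 1:4 / 4, label = c(1, 0, 1, 0))
#' pr_curve(d)$pr_auc  # 5/6
#' @export
pr_curve <- function(data, score = score, label = label,
                     fractions = c(0.05, 0.1, 0.2, 1)) {
  s <- eval_tidy(enquo(score), data)
  l <- check_labels(eval_tidy(enquo(label), data), s)
  P <- sum(l == 1)
  if (P == 0) abort("PR analysis needs at least one positive")
  n <- length(s)
  o <- order(s)
  s <- s[o]; l <- l[o]

  tp_i <- cumsum(l)
  prec_i <- tp_i / seq_len(n)
  rec_i <- tp_i / P

  ends <- cumsum(rle(s)$lengths)
  rec <- rec_i[ends]
  prec <- prec_i[ends]
  pr_auc <- sum(prec * diff(c(0, rec)))

  f_i <- ifelse(tp_i == 0, 0, 2 * prec_i * rec_i / (prec_i + rec_i))
  cut <- pmax(1L, as.integer(round(fractions * n)))
  f_at <- stats::setNames(f_i[cut], paste0("f_", fractions))

  structure(
    list(points = tibble::tibble(recall = rec, precision = prec),
         pr_auc = pr_auc,
         f_curve = tibble::tibble(cutoff = seq_len(n),
                                  fraction = seq_len(n) / n,
                                  precision = prec_i, recall = rec_i,
                                  f = f_i),
         f_at_fraction = f_at,
         mean_f = mean(f_i),
         prevalence = P / n,
         n_pos = P, n = n),
    class = "pr_curve"
  )
}

#' Evaluate a labeled ranking with the full metric panel
#'
#' Bundles the ROC and PR analyses of one scored, labeled ranking into a
#' single row: AUC, raw partial AUC over specificity >= `spec_min`,
#' sensitivity at `spec_min`, PR AUC (average precision), the cumulative
#' F-score at each requested top fraction, and the mean F over all
#' cutoffs.
#'
#' @inheritParams roc_curve
#' @inheritParams pr_curve
#' @return A one-row tibble with columns `n`, `prevalence`, `roc_auc`,
#'   `pauc`, `sens_at_spec`, `pr_auc`, `f_<fraction>`..., `mean_f`.
#' @examples
#' d <- tibble::tibble(score = 1:6 / 6, label = c(1, 0, 1, 0, 0, 0))
#' evaluate_ranking(d)
#' @export
evaluate_ranking <- function(data, score = score, label = label,
                             spec_min = 0.9,
                             fractions = c(0.05, 0.1, 0.2, 1)) {
  sq <- enquo(score); lq <- enquo(label)
  roc <- roc_curve(data, !!sq, !!lq, spec_min = spec_min)
  pr <- pr_curve(data, !!sq, !!lq, fractions = fractions)
  dplyr::bind_cols(
    tibble::tibble(
      n = pr$n, prevalence = pr$prevalence,
      roc_auc = roc$auc, pauc = roc$pauc,
      sens_at_spec = roc$sens_at_spec_min,
      pr_auc = pr$pr_auc
    ),
    tibble::as_tibble(as.list(pr$f_at_fraction)),
    tibble::tibble(mean_f = pr$mean_f)
  )
}
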