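## Ranked-list benchmarking: confusion metrics, ROC/PR curves and areas,
## windowed fold enrichment, and enrichment significance by runs test and
## label permutation.

#' Attach binary labels to a ranked list
#'
#' @param ranking A `"spip_ranking"` (or any data frame with `target`
#'   ordered best-first) or a character vector of targets in rank order.
#' @param positives Set of TP-eligible targets (e.g. an independent
#'   curated holdout).
#' @param source Label-source tag recorded on the result.
#' @return Object of class `"labeled_ranking"`: data frame `rank`,
#'   `target`, `label` (1 = positive).
#' @export
labeled_ranking <- function(ranking, positives, source = "reference") {
  targets <- if (is.data.frame(ranking)) ranking$target else
    as.character(ranking)
  pos <- ref_members(positives)
  out <- data.frame(rank = seq_along(targets), target = targets,
                    label = as.integer(targets %in% pos),
                    stringsAsFactors = FALSE)
  class(out) <- c("labeled_ranking", "data.frame")
  attr(out, "source") <- source
  out
}

lr_labels <- function(ranking) {
  if (inherits(ranking, "labeled_ranking") ||
      (is.data.frame(ranking) && "label" %in% names(ranking))) {
    as.integer(ranking$label)
  } else {
    as.integer(ranking)
  }
}

#' Confusion counts and metrics at a rank cutoff
#'
#' Treats the top `k` of the ranking as predicted positive and computes
#' sensitivity (recall, TP/(TP+FN)), specificity (TN/(TN+FP)) and
#' precision (TP/(TP+FP)).
#'
#' @param ranking A labelled ranking (see [labeled_ranking()]) or a 0/1
#'   label vector in rank order.
#' @param k Cutoff, `1 <= k <= length`.
#' @return Named list of counts and metrics.
#' @export
confusion_at <- function(ranking, k) {
  lab <- lr_labels(ranking)
  n <- length(lab)
  stopifnot(k >= 1L, k <= n)
  P <- sum(lab)
  tp <- sum(lab[seq_len(k)])
  fp <- k - tp
  fn <- P - tp
  tn <- (n - P) - fp
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = if (P > 0) tp / P else NA_real_,
       specificity = if (n - P > 0) tn / (tn + fp) else NA_real_,
       precision = if (k > 0) tp / (tp + fp) else NA_real_)
}

## internal: ROC AUC as the rank (Mann-Whitney) statistic, average ranks
## for ties; scores higher = more positive
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC and precision-recall curves with areas
#'
#' Curve points are computed at every rank threshold; the ROC area equals
#' the Mann-Whitney rank statistic and agrees with the trapezoid rule.
#'
#' @param ranking Labelled ranking or 0/1 label vector in rank order
#'   (best first).
#' @return List with data frames `roc` (`fpr`, `tpr`) and `pr`
#'   (`recall`, `precision`), plus `auc_roc` and `auc_pr`.
#' @export
roc_pr_curves <- function(ranking) {
  lab <- lr_labels(ranking)
  P <- sum(lab)
  N <- length(lab) - P
  if (P == 0L || N == 0L) stop("both classes required")
  tp <- cumsum(lab)
  fp <- seq_along(lab) - tp
  roc <- data.frame(fpr = c(0, fp / N), tpr = c(0, tp / P))
  pr <- data.frame(recall = tp / P, precision = tp / seq_along(lab))
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  # rank AUC on the implied scores (better rank = higher score)
  auc_roc <- auc_rank(-seq_along(lab), lab)
  auc_pr <- trap(c(0, pr$recall), c(pr$precision[1L], pr$precision))
  list(roc = roc, pr = pr, auc_roc = auc_roc, auc_pr = auc_pr)
}

#' Windowed fold enrichment at the top of a ranking
#'
#' Ratio of labelled targets in ranks `1..window` to labelled targets in
#' ranks `window+1..2*window`.
#'
#' @param ranking Labelled ranking or 0/1 label vector.
#' @param window Window size; `2 * window` must not exceed the list
#'   length.
#' @return The fold ratio; `Inf` (flagged by attribute
#'   `denominator_zero`) when the second window has no labelled target,
#'   `NA` when neither window has one.
#' @export
window_fold_enrichment <- function(ranking, window) {
  lab <- lr_labels(ranking)
  if (window < 1L) stop("window must be >= 1")
  if (2L * window > length(lab)) stop("2 * window exceeds list length")
  a <- sum(lab[seq_len(window)])
  b <- sum(lab[window + seq_len(window)])
  if (a == 0L && b == 0L) {
    return(structure(NA_real_, reason = "no labelled targets"))
  }
  if (b == 0L) return(structure(Inf, denominator_zero = TRUE))
  a / b
}

#' TP/FP enrichment at a rank threshold
#'
#' @param ranking Labelled ranking or 0/1 label vector.
#' @param k Rank threshold.
#' @param normalized Divide by the whole-list TP/FP ratio (default
#'   `FALSE`).
#' @return The ratio; `Inf` flagged when no FP at `k`.
#' @export
threshold_enrichment <- function(ranking, k, normalized = FALSE) {
  lab <- lr_labels(ranking)
  stopifnot(k >= 1L, k <= length(lab))
  tp <- sum(lab[seq_len(k)])
  fp <- k - tp
  if (fp == 0L) return(structure(Inf, denominator_zero = TRUE))
  ratio <- tp / fp
  if (normalized) {
    g_tp <- sum(lab)
    g_fp <- length(lab) - g_tp
    ratio <- ratio / (g_tp / g_fp)
  }
  ratio
}

#' Wald-Wolfowitz runs test on the label sequence of a ranking
#'
#' Counts runs of identical labels down the ranked list and refers the
#' count to its normal approximation; few runs indicate clustering of
#' positives (enrichment), many runs indicate alternation.
#'
#' @param ranking Labelled ranking or 0/1 label vector.
#' @return List with `runs`, `z` and two-sided `p`.
#' @export
runs_test <- function(ranking) {
  lab <- lr_labels(ranking)
  n1 <- sum(lab == 1L)
  n0 <- sum(lab == 0L)
  if (n1 == 0L || n0 == 0L) stop("both label classes required")
  if (min(n1, n0) < 10L) {
    warning("fewer than 10 in one class: normal approximation is weak")
  }
  runs <- 1L + sum(diff(lab) != 0L)
  n <- n1 + n0
  mu <- 1 + 2 * n1 * n0 / n
  v <- 2 * n1 * n0 * (2 * n1 * n0 - n) / (n^2 * (n - 1))
  z <- (runs - mu) / sqrt(v)
  list(runs = runs, z = z, p = 2 * pnorm(-abs(z)))
}

#' Permutation test for prefix enrichment
#'
#' Empirical p-value for the number of labelled targets in the top `k`:
#' labels are shuffled `n_perm` times and
#' `p = (1 + #\{perm >= observed\}) / (n_perm + 1)`. Converges to the
#' hypergeometric upper tail.
#'
#' @param ranking Labelled ranking or 0/1 label vector.
#' @param k Prefix size.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return List with `observed`, `p`.
#' @export
random_enrichment_test <- function(ranking, k, n_perm = 1000L, seed = 1L) {
  lab <- lr_labels(ranking)
  stopifnot(n_perm >= 100L, k >= 1L, k <= length(lab))
  obs <- sum(lab[seq_len(k)])
  set.seed(seed)
  hits <- vapply(seq_len(n_perm), function(i) {
    sum(sample(lab)[seq_len(k)]) >= obs
  }, logical(1))
  list(observed = obs, p = (1 + sum(hits)) / (n_perm + 1))
}
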