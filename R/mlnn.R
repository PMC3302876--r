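## Feature-based positive-class prediction: Hobohm-style homology
## reduction, MCC-driven greedy feature-combination search, cross-validated
## feed-forward network ensembles, and combination of two predictor
## versions.

#' Assemble a labelled feature table
#'
#' @param features Numeric proteins x features matrix with rownames.
#' @param labels Named vector/factor with values `"positive"` or
#'   `"negative"` for training proteins; unlabeled proteins carry no
#'   entry.
#' @return Object of class `"feature_table"`.
#' @export
feature_table <- function(features, labels) {
  stopifnot(is.matrix(features), !is.null(rownames(features)),
            !is.null(colnames(features)))
  if (any(!is.finite(features))) stop("non-finite feature values")
  labels <- labels[names(labels) %in% rownames(features)]
  if (!all(labels %in% c("positive", "negative"))) {
    stop("labels must be 'positive' or 'negative'")
  }
  structure(list(features = features, labels = labels),
            class = "feature_table")
}

#' Greedy homology reduction of the labelled set
#'
#' Removes proteins until no retained pair exceeds the similarity
#' threshold, dropping the most-neighboured protein first (ties broken by
#' identifier order), i.e. the retained set is a maximal independent set
#' of the threshold graph.
#'
#' @param table A `"feature_table"`.
#' @param sim Symmetric similarity matrix in `[0, 1]` covering all
#'   labelled proteins (diagonal 1).
#' @param threshold Similarity above which two proteins are "too
#'   similar"; must lie in `(0, 1]`. Default 0.4.
#' @return The reduced `"feature_table"`; attribute `removed` lists the
#'   dropped proteins and `class_ratio` the resulting positive:negative
#'   counts.
#' @export
homology_reduce <- function(table, sim, threshold = 0.4) {
  stopifnot(inherits(table, "feature_table"), is.matrix(sim))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  ids <- names(table$labels)
  if (!all(ids %in% rownames(sim))) stop("similarity matrix must cover all labelled proteins")
  s <- sim[ids, ids, drop = FALSE]
  adj <- s > threshold
  diag(adj) <- FALSE
  removed <- character()
  repeat {
    deg <- rowSums(adj)
    if (all(deg == 0)) break
    worst <- names(sort(deg[deg == max(deg)]))  # candidates at max degree
    drop <- sort(worst)[1L]
    removed <- c(removed, drop)
    keep <- setdiff(rownames(adj), drop)
    adj <- adj[keep, keep, drop = FALSE]
  }
  kept <- setdiff(ids, removed)
  # completion sweep: re-admit any dropped protein whose neighbours were
  # all dropped later, so the retained set is a maximal independent set
  for (p in sort(removed)) {
    if (!any(s[p, kept] > threshold)) {
      kept <- c(kept, p)
      removed <- setdiff(removed, p)
    }
  }
  kept <- ids[ids %in% kept]
  out <- feature_table(table$features, table$labels[kept])
  attr(out, "removed") <- removed
  attr(out, "class_ratio") <- table(factor(table$labels[kept],
                                           c("positive", "negative")))
  out
}

#' Matthews correlation coefficient
#'
#' Balanced two-class quality measure in `[-1, 1]`; by convention 0 when
#' any factor of the denominator is zero.
#'
#' @param tp,fp,tn,fn Confusion counts.
#' @return MCC, or `NA` for an all-zero table.
#' @export
mcc <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fp + tn + fn == 0) return(NA_real_)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

## internal: deterministic fold assignment
make_folds <- function(n, folds, seed) {
  set.seed(seed)
  sample(rep_len(seq_len(folds), n))
}

## internal: train one feed-forward net; one hidden layer of
## max(2, ceiling(d/2)) units, weight decay as a mild regulariser
fit_net <- function(x, y01, seed, size = NULL) {
  if (is.null(size)) size <- max(2L, ceiling(ncol(x) / 2))
  set.seed(seed)
  nnet::nnet(x, y01, size = size, decay = 0.05, maxit = 150,
             trace = FALSE)
}

## internal: cross-validated test MCC for one feature subset
cv_mcc <- function(table, features, folds = 3L, seed = 1L) {
  x <- table$features[names(table$labels), features, drop = FALSE]
  y <- as.integer(table$labels == "positive")
  fold <- make_folds(length(y), folds, seed)
  tp <- fp <- tn <- fn <- 0L
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L) next
    net <- fit_net(x[tr, , drop = FALSE], y[tr], seed = seed * 1000L + f)
    pr <- as.numeric(predict(net, x[!tr, , drop = FALSE])) >= 0.5
    tp <- tp + sum(pr & y[!tr] == 1L)
    fp <- fp + sum(pr & y[!tr] == 0L)
    tn <- tn + sum(!pr & y[!tr] == 0L)
    fn <- fn + sum(!pr & y[!tr] == 1L)
  }
  mcc(tp, fp, tn, fn)
}

#' Greedy MCC-driven feature-combination search
#'
#' Stage 1 ranks single features by cross-validated test MCC; stage 2
#' evaluates pairs of the top singles; stage 3 extends the top pairs to
#' triplets; the search stops as soon as the best new combination fails
#' to beat the incumbent. The top `k` subsets found anywhere in the
#' search are returned.
#'
#' @param table A `"feature_table"` with both classes present.
#' @param folds Cross-validation folds (default 3).
#' @param seed Integer seed controlling folds and network inits.
#' @param top_singles How many top single features feed stage 2.
#' @param k Number of feature subsets to return (default 4).
#' @return List of character vectors (feature subsets), best first, with
#'   attribute `mcc` giving each subset's cross-validated MCC.
#' @export
greedy_feature_search <- function(table, folds = 3L, seed = 1L,
                                  top_singles = 5L, k = 4L) {
  stopifnot(inherits(table, "feature_table"), folds >= 2L)
  if (length(unique(table$labels)) < 2L) {
    stop("both classes required in the labelled set")
  }
  feats <- colnames(table$features)
  evaluated <- list()
  note <- function(subset, m) {
    evaluated[[paste(sort(subset), collapse = "+")]] <<-
      list(subset = subset, mcc = m)
  }
  singles <- vapply(feats, function(f) cv_mcc(table, f, folds, seed),
                    numeric(1))
  for (f in feats) note(f, singles[[f]])
  ord <- names(sort(singles, decreasing = TRUE))
  best <- max(singles)
  top <- head(ord, top_singles)
  # stage 2: pairs of top singles
  stage_sets <- if (length(top) >= 2L) utils::combn(top, 2L, simplify = FALSE)
  else list()
  repeat {
    if (!length(stage_sets)) break
    ms <- vapply(stage_sets, function(s) cv_mcc(table, s, folds, seed),
                 numeric(1))
    for (j in seq_along(stage_sets)) note(stage_sets[[j]], ms[j])
    if (max(ms) <= best) break
    best <- max(ms)
    # stage 3+: extend the well-performing sets by one top single
    good <- stage_sets[ms >= sort(ms, decreasing = TRUE)[min(3L, length(ms))]]
    stage_sets <- list()
    for (s in good) {
      for (f in setdiff(top, s)) {
        cand <- sort(c(s, f))
        if (is.null(evaluated[[paste(cand, collapse = "+")]])) {
          stage_sets <- c(stage_sets, list(cand))
        }
      }
    }
    stage_sets <- unique(stage_sets)
  }
  ms <- vapply(evaluated, `[[`, numeric(1), "mcc")
  sel <- evaluated[order(ms, decreasing = TRUE)][seq_len(min(k, length(ms)))]
  out <- lapply(sel, `[[`, "subset")
  attr(out, "mcc") <- vapply(sel, `[[`, numeric(1), "mcc")
  out
}

#' Train a cross-validated feed-forward network ensemble
#'
#' Trains `nets_per_subset` networks per feature subset (default 3 x 4 =
#' 12 members); the ensemble prediction is the mean member output in
#' `[0, 1]`. Deterministic given the seed.
#'
#' @param table A `"feature_table"`.
#' @param subsets Feature subsets, e.g. from [greedy_feature_search()].
#' @param nets_per_subset Networks per subset (default 3).
#' @param folds Folds for the reported cross-validated MCC (default 3).
#' @param seed Integer seed.
#' @return Object of class `"mlnn_ensemble"` with members, per-subset
#'   cross-validated MCC and training metadata.
#' @export
train_ensemble <- function(table, subsets, nets_per_subset = 3L, folds = 3L,
                           seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (any(!is.finite(table$features))) stop("non-finite feature values")
  x <- table$features[names(table$labels), , drop = FALSE]
  y <- as.integer(table$labels == "positive")
  members <- list()
  for (i in seq_along(subsets)) {
    for (j in seq_len(nets_per_subset)) {
      feats <- subsets[[i]]
      net <- fit_net(x[, feats, drop = FALSE], y,
                     seed = seed * 10000L + i * 100L + j)
      members[[length(members) + 1L]] <- list(net = net, features = feats)
    }
  }
  cv <- vapply(subsets, function(s) cv_mcc(table, s, folds, seed),
               numeric(1))
  structure(list(members = members, subsets = subsets, cv_mcc = cv,
                 folds = folds, seed = seed),
            class = "mlnn_ensemble")
}

#' Predict with an ensemble
#'
#' @param object An `"mlnn_ensemble"`.
#' @param newdata Proteins x features matrix covering every member's
#'   feature subset.
#' @param ... Unused.
#' @return Named numeric vector of mean member outputs in `[0, 1]`.
#' @export
predict.mlnn_ensemble <- function(object, newdata, ...) {
  preds <- vapply(object$members, function(m) {
    as.numeric(predict(m$net, newdata[, m$features, drop = FALSE]))
  }, numeric(nrow(newdata)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  out <- rowMeans(preds)
  pmin(pmax(out, 0), 1) |> setNames(rownames(newdata))
}

#' @export
print.mlnn_ensemble <- function(x, ...) {
  cat(sprintf("Feed-forward ensemble: %d members over %d feature subsets\n",
              length(x$members), length(x$subsets)))
  cat("cross-validated MCC per subset:",
      paste(sprintf("%.3f", x$cv_mcc), collapse = ", "), "\n")
  invisible(x)
}

#' Combine two predictor versions
#'
#' Averages the outputs of two ensembles over their common protein space
#' and reports the ROC AUC of each version and of the combination on an
#' evaluation table.
#'
#' @param v1,v2 Objects of class `"mlnn_ensemble"`.
#' @param eval_features Proteins x features matrix for evaluation.
#' @param eval_labels Named labels (`"positive"`/`"negative"`) on the
#'   evaluation proteins.
#' @return List with the combined `scores` and an `auc` vector
#'   (`v1`, `v2`, `combined`).
#' @export
combine_predictors <- function(v1, v2, eval_features, eval_labels) {
  p1 <- predict(v1, eval_features)
  p2 <- predict(v2, eval_features)
  common <- intersect(names(p1), names(p2))
  if (!length(common)) stop("predictors cover disjoint protein sets")
  scores <- (p1[common] + p2[common]) / 2
  lab <- as.integer(eval_labels[common] == "positive")
  aucs <- c(v1 = auc_rank(p1[common], lab),
            v2 = auc_rank(p2[common], lab),
            combined = auc_rank(scores, lab))
  list(scores = scores, auc = aucs)
}
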