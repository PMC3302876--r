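# labelled table with d features; first `informative` features separate
# the classes by `shift` standard deviations
make_table <- function(n_pos = 20, n_neg = 40, d = 6, informative = 1,
                       shift = 3, seed = 1) {
  set.seed(seed)
  n <- n_pos + n_neg
  ids <- sprintf("q%03d", seq_len(n))
  x <- base::matrix(rnorm(n * d), nrow = n,
                    dimnames = list(ids, sprintf("F%02d", seq_len(d))))
  lab <- setNames(c(rep("positive", n_pos), rep("negative", n_neg)), ids)
  x[lab == "positive", seq_len(informative)] <-
    x[lab == "positive", seq_len(informative)] + shift
  feature_table(x, lab)
}

test_that("homology reduction yields a maximal independent set", {
  tab <- make_table(n_pos = 8, n_neg = 12, seed = 2)
  ids <- names(tab$labels)
  n <- length(ids)
  set.seed(5)
  sim <- base::matrix(runif(n * n), n, n, dimnames = list(ids, ids))
  sim[lower.tri(sim)] <- t(sim)[lower.tri(sim)]
  diag(sim) <- 1
  red <- homology_reduce(tab, sim, threshold = 0.8)
  kept <- names(red$labels)
  adj <- sim > 0.8; diag(adj) <- FALSE
  # independence: no retained pair above threshold
  expect_false(any(adj[kept, kept]))
  # maximality: every dropped protein conflicts with a retained one
  for (p in setdiff(ids, kept)) expect_true(any(adj[p, kept]))
  # identical proteins: exactly one survives
  sim2 <- diag(n); dimnames(sim2) <- list(ids, ids)
  sim2[1, 2] <- sim2[2, 1] <- 1
  red2 <- homology_reduce(tab, sim2, threshold = 0.9)
  expect_equal(sum(c(ids[1], ids[2]) %in% names(red2$labels)), 1L)
  # nothing above threshold: identity
  red3 <- homology_reduce(tab, sim2, threshold = 1)
  expect_setequal(names(red3$labels), ids)
  expect_error(homology_reduce(tab, sim, threshold = 0), "threshold")
})

test_that("MCC matches the closed formula and its conventions", {
  expect_equal(mcc(10, 0, 10, 0), 1)
  expect_equal(mcc(0, 10, 0, 10), -1)
  expect_equal(mcc(3, 1, 4, 2), (3 * 4 - 1 * 2) / sqrt(4 * 5 * 5 * 6))
  expect_equal(mcc(5, 5, 0, 0), 0)    # zero denominator factor
  expect_true(is.na(mcc(0, 0, 0, 0)))
})

test_that("greedy search finds a planted feature and stops on noise", {
  tab <- make_table(informative = 1, shift = 3, seed = 3)
  subsets <- greedy_feature_search(tab, seed = 7)
  expect_true("F01" %in% subsets[[1]])
  expect_gt(attr(subsets, "mcc")[1], 0.7)

  noise <- make_table(informative = 0, shift = 0, seed = 4)
  s2 <- greedy_feature_search(noise, seed = 7)
  expect_lt(max(attr(s2, "mcc")), 0.45)
  one_class <- feature_table(tab$features,
                             tab$labels[tab$labels == "positive"])
  expect_error(greedy_feature_search(one_class, seed = 1), "both classes")
})

test_that("jointly informative features beat their singles", {
  set.seed(9)
  n <- 120
  ids <- sprintf("x%03d", 1:n)
  x <- base::matrix(rnorm(n * 4), nrow = n,
                    dimnames = list(ids, c("Fa", "Fb", "Fc", "Fd")))
  lab <- setNames(ifelse(xor(x[, "Fa"] > 0, x[, "Fb"] > 0),
                         "positive", "negative"), ids)
  tab <- feature_table(x, lab)
  m_a <- cv_mcc_for_test(tab, "Fa")
  m_b <- cv_mcc_for_test(tab, "Fb")
  m_ab <- cv_mcc_for_test(tab, c("Fa", "Fb"))
  expect_gt(m_ab, max(m_a, m_b) + 0.2)
})

test_that("ensembles separate a planted class and collapse under permutation", {
  tab <- make_table(n_pos = 25, n_neg = 50, informative = 2, shift = 2.5,
                    seed = 11)
  subsets <- list(c("F01", "F02"))
  ens <- train_ensemble(tab, subsets, nets_per_subset = 3, seed = 5)
  expect_gt(ens$cv_mcc[1], 0.8)
  sc <- predict(ens, tab$features)
  expect_true(all(sc >= 0 & sc <= 1))
  # deterministic given the seed
  ens2 <- train_ensemble(tab, subsets, nets_per_subset = 3, seed = 5)
  expect_identical(predict(ens2, tab$features), sc)
  # column order of the prediction matrix is irrelevant
  shuf <- tab$features[, rev(colnames(tab$features))]
  expect_equal(predict(ens, shuf), sc)
  # label permutation destroys the signal
  set.seed(13)
  perm <- tab
  names(perm$labels) <- sample(names(perm$labels))
  perm <- feature_table(tab$features, perm$labels)
  ens_p <- train_ensemble(perm, subsets, nets_per_subset = 3, seed = 5)
  expect_lt(abs(ens_p$cv_mcc[1]), 0.4)
})

test_that("a single-member ensemble equals its one network", {
  tab <- make_table(seed = 15)
  ens <- train_ensemble(tab, list("F01"), nets_per_subset = 1, seed = 3)
  expect_length(ens$members, 1L)
  direct <- as.numeric(predict(ens$members[[1]]$net,
                               tab$features[, "F01", drop = FALSE]))
  expect_equal(unname(predict(ens, tab$features)), direct)
})

test_that("combining two predictor versions reports coherent AUCs", {
  tab <- make_table(n_pos = 25, n_neg = 50, informative = 2, shift = 2,
                    seed = 17)
  v1 <- train_ensemble(tab, list("F01"), nets_per_subset = 2, seed = 1)
  v2 <- train_ensemble(tab, list("F02"), nets_per_subset = 2, seed = 2)
  out <- combine_predictors(v1, v2, tab$features, tab$labels)
  expect_true(all(out$auc >= 0 & out$auc <= 1))
  # combining a model with itself reproduces it
  same <- combine_predictors(v1, v1, tab$features, tab$labels)
  expect_equal(unname(same$scores),
               unname(predict(v1, tab$features)))
  expect_equal(same$auc[["combined"]], same$auc[["v1"]])
  # AUC agrees with the independent reference implementation
  lab01 <- as.integer(tab$labels == "positive")
  expect_equal(out$auc[["combined"]],
               as.numeric(pROC::auc(lab01, unname(out$scores),
                                    quiet = TRUE)))
})
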