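test_that("confusion metrics match exhaustive counting at every cutoff", {
  set.seed(2)
  lab <- sample(c(0, 1), 50, replace = TRUE, prob = c(0.7, 0.3))
  P <- sum(lab); N <- 50 - P
  for (k in seq_len(50)) {
    cm <- confusion_at(lab, k)
    tp <- sum(lab[1:k] == 1)
    expect_equal(cm$tp, tp)
    expect_equal(cm$fp, k - tp)
    expect_equal(cm$fn, P - tp)
    expect_equal(cm$tn, N - (k - tp))
    expect_equal(cm$sensitivity, tp / P)
    expect_equal(cm$precision, tp / k)
  }
  expect_equal(confusion_at(lab, 50)$sensitivity, 1)
  perfect <- c(rep(1, P), rep(0, N))
  expect_equal(confusion_at(perfect, P)$precision, 1)
})

test_that("ROC area equals the rank statistic, trapezoid and pair oracle", {
  set.seed(4)
  lab <- sample(c(rep(1, 12), rep(0, 28)))
  cv <- roc_pr_curves(lab)
  # implied scores decrease with rank
  sc <- -seq_along(lab)
  expect_equal(cv$auc_roc, bf_auc(sc, lab))
  expect_equal(cv$auc_roc, bf_trapezoid(cv$roc$fpr, cv$roc$tpr),
               tolerance = 1e-12)
  expect_equal(cv$auc_roc,
               as.numeric(pROC::auc(lab, sc, quiet = TRUE)))
  expect_equal(roc_pr_curves(c(1, 1, 0, 0))$auc_roc, 1)
  expect_error(roc_pr_curves(rep(1, 5)), "both classes")
  # invariance under strictly monotone transforms is inherent: the curve
  # depends on the ordering only
  expect_equal(roc_pr_curves(lab)$auc_roc, cv$auc_roc)
})

test_that("label shuffling centres the AUC on one half", {
  set.seed(7)
  lab <- c(rep(1, 10), rep(0, 40))
  aucs <- replicate(200, roc_pr_curves(sample(lab))$auc_roc)
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
  expect_gt(min(aucs), 0.15)
  expect_lt(max(aucs), 0.85)
})

test_that("window fold enrichment is the ratio of labelled window counts", {
  lab <- c(rep(1, 10), rep(0, 40), rep(1, 5), rep(0, 45))
  expect_equal(window_fold_enrichment(lab, 50), 10 / 5)
  expect_equal(window_fold_enrichment(c(1, 0, 1, 0), 2), 1)
  none <- rep(0, 20)
  expect_true(is.na(window_fold_enrichment(none, 10)))
  only_first <- c(1, rep(0, 19))
  expect_true(is.infinite(window_fold_enrichment(only_first, 10)))
  expect_error(window_fold_enrichment(lab, 0), "window")
  expect_error(window_fold_enrichment(lab, 51), "exceeds")
})

test_that("threshold enrichment counts TP/FP with normalisation", {
  lab <- c(1, 1, 1, 0, 1, 0, 0, 0, 1, 0)
  expect_true(is.infinite(threshold_enrichment(lab, 3)))
  expect_equal(threshold_enrichment(lab, 6), 4 / 2)
  # prefix ratio equal to the global ratio normalises to 1
  expect_equal(threshold_enrichment(lab, 10, normalized = TRUE), 1)
  set.seed(11)
  rl <- sample(c(0, 1), 30, replace = TRUE)
  for (k in c(5, 12, 30)) {
    tp <- sum(rl[1:k]); fp <- k - tp
    if (fp > 0) expect_equal(threshold_enrichment(rl, k), tp / fp)
  }
})

test_that("runs test flags sorted and alternating extremes", {
  alt <- rep(c(1, 0), 20)
  r1 <- runs_test(alt)
  expect_equal(r1$runs, 40L)
  expect_gt(r1$z, 4)
  sorted <- c(rep(1, 20), rep(0, 20))
  r2 <- runs_test(sorted)
  expect_equal(r2$runs, 2L)
  expect_lt(r2$z, -4)
  expect_lt(r2$p, 1e-4)
  expect_warning(runs_test(c(1, rep(0, 30))), "fewer than 10")
  expect_error(runs_test(rep(1, 10)), "both label classes")
})

test_that("runs-test p-values are calibrated under shuffling", {
  # the runs count is discrete, so its p-value is only approximately
  # uniform: check the rejection rate and the mean rather than exact
  # distributional identity
  set.seed(13)
  lab <- c(rep(1, 150), rep(0, 150))
  ps <- replicate(500, runs_test(sample(lab))$p)
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
  expect_gt(mean(ps), 0.42)
  expect_lt(mean(ps), 0.58)
})

test_that("permutation enrichment matches the hypergeometric tail", {
  set.seed(17)
  lab <- sample(c(rep(1, 8), rep(0, 18)))
  k <- 7
  out <- random_enrichment_test(lab, k, n_perm = 4000, seed = 3)
  obs <- sum(lab[1:k])
  exact <- phyper(obs - 1, 8, 18, k, lower.tail = FALSE)
  expect_equal(out$p, exact, tolerance = 0.03)
  # extreme prefix concentration gives a small p
  ext <- c(rep(1, 8), rep(0, 18))
  expect_lt(random_enrichment_test(ext, 8, n_perm = 500, seed = 1)$p, 0.01)
  # uniform placement centres the p-value
  set.seed(19)
  meds <- replicate(40, {
    random_enrichment_test(sample(lab), 13, n_perm = 200,
                           seed = sample.int(1e6, 1))$p
  })
  expect_gt(median(meds), 0.2)
  expect_lt(median(meds), 0.95)
  expect_error(random_enrichment_test(lab, 5, n_perm = 10), "n_perm")
})

test_that("labelled rankings attach labels in rank order", {
  r <- data.frame(target = c("a", "b", "c", "d"))
  lr <- labeled_ranking(r, c("b", "d"))
  expect_equal(lr$label, c(0L, 1L, 0L, 1L))
  expect_equal(lr$rank, 1:4)
})
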