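test_that("empirical p-values follow the add-one right-tail estimator", {
  set.seed(1)
  s <- rnorm(50)
  p <- empirical_pvalue(setNames(s, sprintf("t%02d", 1:50)))
  n <- length(s)
  expect_equal(unname(p[which.max(s)]), 2 / (n + 1))
  expect_equal(unname(p[which.min(s)]), 1)
  # monotone non-increasing in the score
  ord <- order(s, decreasing = TRUE)
  expect_true(all(diff(p[ord]) >= 0))
  # all-identical scores flag and give p = 1
  expect_warning(p1 <- empirical_pvalue(rep(3, 5)), "identical")
  expect_equal(unname(p1), rep(1, 5))
})

test_that("empirical p-values of uniform scores are themselves uniform", {
  rejections <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    p <- empirical_pvalue(runif(60))
    ks <- suppressWarnings(ks.test(p, "punif"))
    if (ks$p.value < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 3L)
})

test_that("Fisher combination matches independent oracles", {
  expect_equal(fisher_combine(0.2), 0.2)       # single p passes through
  expect_equal(fisher_combine(c(1, 1, 1)), 1)
  # closed form for two p-values: t - t log t with t = p1 p2
  t <- 0.05 * 0.05
  expect_equal(fisher_combine(c(0.05, 0.05)), t - t * log(t),
               tolerance = 1e-12)
  # quadrature oracle: P(U1 U2 <= t) = integral of min(1, t/u) du
  quad <- stats::integrate(function(u) pmin(1, t / u), 0, 1,
                           rel.tol = 1e-12)$value
  expect_equal(fisher_combine(c(0.05, 0.05)), quad, tolerance = 1e-10)
  # exchangeability
  ps <- c(0.3, 0.02, 0.77)
  expect_equal(fisher_combine(ps), fisher_combine(rev(ps)))
  expect_error(fisher_combine(c(0.5, 0)), "0, 1")
  expect_error(fisher_combine(numeric()), "empty")
})

test_that("two-stage integration matches a straight-line reference", {
  set.seed(23)
  ch <- names(channel_approaches())
  m <- base::matrix(runif(30 * length(ch)), nrow = 30,
                    dimnames = list(sprintf("t%02d", 1:30), ch))
  m[sample(length(m), 40)] <- NA             # random missingness
  keep <- rowSums(!is.na(m)) > 0
  r <- spip_integrate(m)
  ap <- channel_approaches()[colnames(m)]
  for (k in seq_len(nrow(r))) {
    row <- m[r$target[k], ]
    expect_equal(r$p_spip[k], bf_two_stage(row, ap))
  }
  # sorted ascending with deterministic tie-breaks
  expect_true(all(diff(r$p_spip) >= 0))
  expect_equal(r$rank, seq_len(nrow(r)))
})

test_that("degenerate integration cases behave as documented", {
  m <- base::matrix(c(0.3, 0.8), ncol = 1,
                    dimnames = list(c("a", "b"), "GECO"))
  r <- spip_integrate(m)
  expect_equal(sort(r$p_spip), sort(c(0.3, 0.8)))  # single channel
  # identical p across all channels reinforces
  ch <- names(channel_approaches())
  m2 <- base::matrix(0.05, nrow = 1, ncol = length(ch),
                     dimnames = list("a", ch))
  r2 <- spip_integrate(m2)
  expect_lt(r2$p_spip, 0.05)
  # targets with no channel are excluded with a message
  m3 <- base::matrix(c(0.2, NA), ncol = 1,
                     dimnames = list(c("a", "b"), "GECO"))
  expect_message(r3 <- spip_integrate(m3), "excluded")
  expect_equal(r3$target, "a")
  # flat mode equals one Fisher across all channels
  m4 <- base::matrix(runif(4), nrow = 1,
                     dimnames = list("a", ch[1:4]))
  expect_equal(spip_integrate(m4, mode = "flat")$p_spip,
               fisher_combine(m4[1, ]))
})

test_that("uniform independent channels give uniform platform p-values", {
  ch <- names(channel_approaches())
  rejections <- 0L
  for (seed in 1:10) {
    set.seed(300 + seed)
    m <- base::matrix(runif(400 * length(ch)), nrow = 400,
                      dimnames = list(sprintf("t%03d", 1:400), ch))
    r <- spip_integrate(m)
    ks <- suppressWarnings(ks.test(r$p_spip, "punif"))
    if (ks$p.value < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 1L)
})

test_that("calibration diagnostics pass uniform and catch shifted samples", {
  set.seed(5)
  ok <- calibration_check(runif(200))
  expect_true(ok$pass)
  bad <- calibration_check(rbeta(200, 0.3, 1))
  expect_false(bad$pass)
  expect_error(calibration_check(runif(10)), "at least 30")
})

test_that("MI distance is a normalised metric with the documented poles", {
  x <- rep(1:2, each = 30)
  expect_equal(mi_distance(x, x), 0)          # x determines y
  # exact product joint: independence
  g <- expand.grid(a = 1:2, b = 1:3)
  expect_equal(mi_distance(rep(g$a, 10), rep(g$b, 10)), 1)
  # hand-computed 2x2 joint (10, 5; 5, 10)
  tab <- base::matrix(c(10, 5, 5, 10), 2)
  x2 <- rep(c(1, 1, 2, 2), times = as.vector(tab))
  y2 <- rep(c(1, 2, 1, 2), times = as.vector(tab))
  want <- bf_mi(tab)
  expect_equal(mi_distance(x2, y2), want$D)
  expect_equal(mi_distance(y2, x2), want$D)   # symmetry
  expect_error(mi_distance(rep(1, 10), rep(2, 10)), "constant")
})

test_that("MI distance satisfies the triangle inequality on random triples", {
  set.seed(29)
  for (rep in 1:25) {
    x <- sample(1:3, 60, replace = TRUE)
    y <- sample(1:3, 60, replace = TRUE)
    z <- sample(1:3, 60, replace = TRUE)
    dxy <- mi_distance(x, y)
    dyz <- mi_distance(y, z)
    dxz <- mi_distance(x, z)
    expect_lte(dxz, dxy + dyz + 1e-9)
  }
})

test_that("channel MI distance matrix is symmetric with zero diagonal", {
  set.seed(33)
  m <- base::matrix(runif(200 * 3), ncol = 3,
                    dimnames = list(sprintf("t%03d", 1:200),
                                    c("GECO", "GOSS", "MLNN")))
  m[, "GOSS"] <- pmin(1, pmax(1e-6, m[, "GECO"] + runif(200, 0, 0.05)))
  D <- channel_mi_distances(m)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))
  # a nearly determined channel pair sits far below an independent one
  expect_lt(D["GECO", "GOSS"], D["GECO", "MLNN"])
})
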