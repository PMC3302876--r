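test_that("physical filtering keeps exactly the tagged edges", {
  e <- data.frame(p1 = c("a", "a", "b", "c", "d"),
                  p2 = c("b", "c", "c", "d", "e"),
                  relation_class = c("physical", "genetic", "physical",
                                     "regulatory", "physical"))
  g <- filter_physical(cocite_network(e))
  expect_equal(igraph::ecount(g), 3L)

  all_phys <- e
  all_phys$relation_class <- "physical"
  g2 <- filter_physical(cocite_network(all_phys))
  expect_equal(igraph::ecount(g2), nrow(e))

  expect_error(filter_physical(cocite_network(e[, 1:2])), "relation_class")
})

test_that("physical filtering agrees with a brute-force tag scan", {
  e <- rand_tagged_graph(12, 0.3, seed = 7)
  g <- filter_physical(cocite_network(e))
  keep <- e[e$relation_class == "physical", ]
  got <- apply(igraph::as_edgelist(g), 1L,
               function(r) paste(sort(r), collapse = "|"))
  want <- apply(keep[, c("p1", "p2")], 1L,
                function(r) paste(sort(r), collapse = "|"))
  expect_setequal(got, unique(want))
})

test_that("S1 and S2 match hand evaluation on brute-force counts", {
  e <- data.frame(p1 = c("i", "i", "i", "r1", "c1", "c1"),
                  p2 = c("r1", "r2", "c1", "x", "r2", "r3"),
                  relation_class = "physical")
  g <- filter_physical(cocite_network(e))
  ref <- c("r1", "r2", "r3")
  ct <- bf_s1_counts(e, ref, "i")
  expect_equal(s1_score(g, ref, "i"),
               ct$n_ri^2 / (ct$N_r * ct$N_i))
  ct2 <- bf_s2_counts(e, ref, "i")
  expect_equal(s2_score(g, ref, "i"),
               ct2$n_rci^2 / (ct2$N_r2 * ct2$N_c * ct2$N_i))
  # no reference neighbours forces 0
  expect_equal(s1_score(g, "r3", "i"), 0)
})

test_that("S2 path counts match BFS enumeration on random graphs", {
  for (seed in 1:3) {
    e <- rand_tagged_graph(12, 0.35, seed = seed,
                           classes = "physical")
    g <- filter_physical(cocite_network(e))
    ids <- igraph::V(g)$name
    ref <- ids[1:4]
    for (i in setdiff(ids, ref)[1:4]) {
      ct <- bf_s2_counts(e, ref, i)
      want <- if (ct$n_rci == 0) 0 else
        ct$n_rci^2 / (ct$N_r2 * ct$N_c * ct$N_i)
      expect_equal(s2_score(g, ref, i), want)
    }
  }
})

test_that("path graph r-c-i gives the single-path S2 value", {
  e <- data.frame(p1 = c("r", "c"), p2 = c("c", "i"),
                  relation_class = "physical")
  g <- filter_physical(cocite_network(e))
  # one path, all degrees along it: N_r = 1, N_c = 2, N_i = 1
  expect_equal(s2_score(g, "r", "i"), 1 / (1 * 2 * 1))
  expect_equal(s1_score(g, "r", "i"), 0)
})

test_that("sticky neighbours never increase S1", {
  set.seed(11)
  for (rep in 1:5) {
    e <- rand_tagged_graph(14, 0.3, seed = 20 + rep, classes = "physical")
    ids <- unique(c(e$p1, e$p2))
    ref <- ids[1:4]
    i <- setdiff(ids, ref)[1L]
    g <- filter_physical(cocite_network(e))
    before <- s1_score(g, ref, i)
    # attach i to a new high-degree non-reference hub
    hub_edges <- data.frame(p1 = "hub", p2 = setdiff(ids, c(i, ref))[1:3],
                            relation_class = "physical")
    e2 <- rbind(e, hub_edges,
                data.frame(p1 = i, p2 = "hub",
                           relation_class = "physical"))
    g2 <- filter_physical(cocite_network(e2))
    expect_lte(s1_score(g2, ref, i), before)
  }
})

test_that("scores are invariant under protein relabelling", {
  e <- rand_tagged_graph(10, 0.4, seed = 5, classes = "physical")
  ids <- unique(c(e$p1, e$p2))
  perm <- setNames(sprintf("z%02d", seq_along(ids)), ids)
  e2 <- data.frame(p1 = perm[e$p1], p2 = perm[e$p2],
                   relation_class = "physical")
  ref <- ids[1:3]
  i <- setdiff(ids, ref)[1L]
  g <- filter_physical(cocite_network(e))
  g2 <- filter_physical(cocite_network(e2))
  expect_equal(s1_score(g2, unname(perm[ref]), unname(perm[i])),
               s1_score(g, ref, i))
  expect_equal(s2_score(g2, unname(perm[ref]), unname(perm[i])),
               s2_score(g, ref, i))
})

test_that("score_all_cocite composes per-node scores and excludes the reference", {
  e <- data.frame(p1 = c("r1", "r2", "x"), p2 = c("x", "x", "y"),
                  relation_class = "physical")
  g <- filter_physical(cocite_network(e))
  out <- score_all_cocite(g, c("r1", "r2"))
  expect_setequal(out$d$target, c("x", "y"))
  expect_equal(out$d$score[out$d$target == "x"],
               s1_score(g, c("r1", "r2"), "x"))
  expect_equal(out$i$score[out$i$target == "y"],
               s2_score(g, c("r1", "r2"), "y"))
  # reference-only network leaves nothing to score
  ref_only <- filter_physical(cocite_network(
    data.frame(p1 = "r1", p2 = "r2", relation_class = "physical")))
  empty <- score_all_cocite(ref_only, c("r1", "r2"))
  expect_equal(nrow(empty$d), 0L)
})

test_that("direct co-citation separates a planted module", {
  b <- generate_bundle(small_params(), seed = 9)
  g <- filter_physical(cocite_network(b$cocite_edges))
  out <- score_all_cocite(g, b$seed_set)$d
  lab <- as.integer(out$target %in% b$holdout$members)
  expect_gt(bf_auc(out$score, lab), 0.7)
})
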