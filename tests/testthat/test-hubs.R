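toy_channel_pairs <- function() {
  data.frame(
    p1 = c("a", "a", "a", "b", "c"),
    p2 = c("x", "x", "y", "y", "z"),
    channel = c("GECO", "hiPPI", "GECO", "CODAcath", "GECO"),
    p = c(0.001, 0.01, 0.5, 0.013, 0.014),
    stringsAsFactors = FALSE)
}

test_that("predicted graph keeps gated pairs and unions channel tags", {
  pg <- build_pg(toy_channel_pairs())
  expect_equal(igraph::ecount(pg), 3L)
  eid <- igraph::get_edge_ids(pg, c("a", "x"))
  expect_equal(igraph::E(pg)$sources[eid], "GECO,hiPPI")
  # nothing passes an extreme gate
  strict <- build_pg(toy_channel_pairs(), p_gate = 1e-6)
  expect_equal(igraph::ecount(strict), 0L)
  expect_error(build_pg(toy_channel_pairs(), p_gate = 0), "gate")
})

test_that("relaxing the gate only grows the predicted graph", {
  set.seed(3)
  cp <- data.frame(p1 = sample(letters[1:10], 60, TRUE),
                   p2 = sample(letters[11:20], 60, TRUE),
                   channel = sample(c("GECO", "hiPPI"), 60, TRUE),
                   p = runif(60), stringsAsFactors = FALSE)
  prev <- 0L
  for (gate in c(0.01, 0.05, 0.2, 1)) {
    pg <- build_pg(cp, gate)
    expect_gte(igraph::ecount(pg), prev)
    prev <- igraph::ecount(pg)
    # brute-force union-filter
    keep <- cp[cp$p <= gate, ]
    want <- unique(apply(keep[, c("p1", "p2")], 1L,
                         function(r) paste(sort(r), collapse = "|")))
    got <- apply(igraph::as_edgelist(pg), 1L,
                 function(r) paste(sort(r), collapse = "|"))
    expect_setequal(got, want)
  }
})

test_that("top-fraction selection uses floor arithmetic", {
  expect_length(select_top_fraction(sprintf("p%d", 1:100), 0.025), 2L)
  expect_length(select_top_fraction(sprintf("p%d", 1:100), 1), 100L)
  expect_equal(select_top_fraction(c("a", "b", "c"), 0.5), "a")
  expect_error(select_top_fraction(letters, 0), "fraction")
})

test_that("degree records match brute-force adjacency counts", {
  set.seed(5)
  kg_e <- data.frame(p1 = sample(letters[1:12], 30, TRUE),
                     p2 = sample(letters[1:12], 30, TRUE),
                     source = "db", stringsAsFactors = FALSE)
  kg_e <- kg_e[kg_e$p1 != kg_e$p2, ]
  pg_e <- data.frame(p1 = sample(letters[1:12], 40, TRUE),
                     p2 = sample(letters[1:12], 40, TRUE),
                     channel = "GECO", p = 0.001, stringsAsFactors = FALSE)
  pg_e <- pg_e[pg_e$p1 != pg_e$p2, ]
  kg <- evidence_graph(kg_e)
  pg <- build_pg(pg_e)
  spindle <- c("a", "b", "c")
  rec <- degree_stats(letters[1:12], kg, pg, spindle)
  simple <- function(e) unique(t(apply(e, 1L, sort)))
  kg_s <- simple(kg_e[, 1:2]); pg_s <- simple(pg_e[, 1:2])
  for (k in seq_len(nrow(rec))) {
    v <- rec$protein[k]
    expect_equal(rec$kg_degree[k], sum(kg_s == v))
    expect_equal(rec$pg_degree[k], sum(pg_s == v))
    nb <- unique(c(pg_s[pg_s[, 1] == v, 2], pg_s[pg_s[, 2] == v, 1]))
    expect_equal(rec$spindle_degree_pg[k], length(intersect(nb, spindle)))
  }
  # isolated candidate: zeros and flagged fraction
  iso <- degree_stats("zzz", kg, pg, spindle)
  expect_equal(iso$kg_degree, 0L)
  expect_equal(iso$pg_degree, 0L)
  expect_true(is.na(iso$spindle_fraction))
})

test_that("hidden-hub filter applies the five-fold rule exactly", {
  rec <- data.frame(
    protein = c("even", "hub", "known", "unspecific"),
    kg_degree = c(10L, 0L, 20L, 1L),
    pg_degree = c(10L, 40L, 100L, 30L),
    spindle_degree_pg = c(9L, 36L, 90L, 6L),
    spindle_fraction = c(0.9, 0.9, 0.9, 0.2),
    stringsAsFactors = FALSE)
  hubs <- hidden_hub_rank(rec)
  # ratio 1 < 5 excluded; high KG excluded; low specificity excluded
  expect_equal(hubs$protein, "hub")
  expect_true(all(hubs$pg_degree >= 5 * pmax(hubs$kg_degree, 1)))
  # brute-force predicate scan on random records
  set.seed(7)
  rr <- data.frame(protein = sprintf("r%02d", 1:40),
                   kg_degree = sample(0:12, 40, TRUE),
                   pg_degree = sample(0:60, 40, TRUE))
  rr$spindle_degree_pg <- floor(rr$pg_degree * runif(40))
  rr$spindle_fraction <- ifelse(rr$pg_degree > 0,
                                rr$spindle_degree_pg / rr$pg_degree, NA)
  got <- hidden_hub_rank(rr, min_ratio = 5, max_kg_degree = 5,
                         min_spindle_fraction = 0.5)
  want <- rr[rr$kg_degree <= 5 &
               rr$pg_degree >= 5 * pmax(rr$kg_degree, 1) &
               !is.na(rr$spindle_fraction) &
               rr$spindle_fraction >= 0.5, ]
  expect_setequal(got$protein, want$protein)
  # ranked by predicted degree, then specificity
  expect_true(all(diff(got$pg_degree) <= 0))
})

test_that("a planted hidden hub is recovered at rank one", {
  fx <- generate_hub_fixture(seed = 42)
  kg <- evidence_graph(fx$kg_edges)
  pg <- build_pg(fx$channel_pairs)
  rec <- degree_stats(fx$candidates, kg, pg, fx$module)
  hubs <- hidden_hub_rank(rec)
  expect_equal(hubs$protein[1], fx$hub)
  hub_row <- rec[rec$protein == fx$hub, ]
  expect_true(hub_row$pg_degree >= 5 * max(hub_row$kg_degree, 1))
})
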