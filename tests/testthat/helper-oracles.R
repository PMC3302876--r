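# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own code paths:
# counting is done with plain loops over edge lists and tables.

# --- graph oracles -------------------------------------------------------

# neighbours of v in a plain edge data frame (p1, p2)
bf_neighbours <- function(edges, v) {
  unique(c(edges$p2[edges$p1 == v], edges$p1[edges$p2 == v]))
}

bf_degree <- function(edges, v) length(bf_neighbours(edges, v))

# direct co-citation counts by exhaustive scan
bf_s1_counts <- function(edges, ref, i) {
  nb <- bf_neighbours(edges, i)
  r <- intersect(nb, ref)
  list(n_ri = length(r),
       N_r = sum(vapply(r, bf_degree, numeric(1), edges = edges)),
       N_i = bf_degree(edges, i))
}

# indirect counts by enumerating all length-2 paths i - c - r
bf_s2_counts <- function(edges, ref, i) {
  nb <- bf_neighbours(edges, i)
  n_rci <- 0L
  cons <- character()
  rs <- character()
  for (c in nb) {
    hits <- setdiff(intersect(bf_neighbours(edges, c), ref), i)
    if (length(hits)) {
      n_rci <- n_rci + length(hits)
      cons <- union(cons, c)
      rs <- union(rs, hits)
    }
  }
  list(n_rci = n_rci,
       N_r2 = sum(vapply(rs, bf_degree, numeric(1), edges = edges)),
       N_c = sum(vapply(cons, bf_degree, numeric(1), edges = edges)),
       N_i = bf_degree(edges, i))
}

# random simple tagged graph as an edge data frame
rand_tagged_graph <- function(n, p, seed, classes = c("physical", "genetic")) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p) {
        rows[[length(rows) + 1L]] <- data.frame(
          p1 = ids[i], p2 = ids[j],
          relation_class = sample(classes, 1L), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# --- ranking oracles -----------------------------------------------------

# AUC by exhaustive positive/negative pair comparison
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# trapezoid area under an ROC curve data frame
bf_trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

# --- integration oracles -------------------------------------------------

# straight-line two-stage Fisher, written independently of the package
bf_two_stage <- function(p_row, approach_of) {
  fisher1 <- function(p) {
    pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
  }
  ap <- c()
  for (a in unique(approach_of)) {
    v <- p_row[!is.na(p_row) & approach_of == a]
    if (length(v)) ap <- c(ap, fisher1(v))
  }
  fisher1(ap)
}

# plug-in MI quantities from a joint count table
bf_mi <- function(tab) {
  pj <- tab / sum(tab)
  px <- rowSums(pj)
  py <- colSums(pj)
  I <- 0; H <- 0
  for (i in seq_len(nrow(pj))) {
    for (j in seq_len(ncol(pj))) {
      if (pj[i, j] > 0) {
        H <- H - pj[i, j] * log(pj[i, j])
        I <- I + pj[i, j] * log(pj[i, j] / (px[i] * py[j]))
      }
    }
  }
  list(I = I, H = H, D = 1 - I / H)
}

# --- ontology oracle -----------------------------------------------------

# ancestors (incl. self) by iterated parent lookup over the edge table
bf_ancestors <- function(edges, term) {
  anc <- term
  repeat {
    more <- unique(edges$parent[edges$child %in% anc])
    new <- setdiff(more, anc)
    if (!length(new)) break
    anc <- c(anc, new)
  }
  anc
}

# --- hippi oracle --------------------------------------------------------

# slow per-pair hiPPI score by direct enumeration over known interactions
bf_hippi <- function(a, b, cl, known) {
  lev <- function(x, y) {
    ia <- match(x, cl$protein); ib <- match(y, cl$protein)
    if (cl$family[ia] != cl$family[ib]) return(NA_integer_)
    if (ia == ib) return(ncol(cl$levels))
    eq <- cl$levels[ia, ] == cl$levels[ib, ]
    if (!any(eq)) return(NA_integer_)
    max(which(eq))
  }
  total <- NA_real_
  for (k in seq_len(nrow(known))) {
    n_ev <- length(strsplit(known$evidence_types[k], ",")[[1]])
    n_sp <- length(strsplit(known$species[k], ",")[[1]])
    extras <- (n_ev - 1) + (n_sp - 1)
    mult <- 1 + if (extras > 0) sum(0.5^seq_len(extras)) else 0
    best <- NA_real_
    for (or in list(c(known$p1[k], known$p2[k]),
                    c(known$p2[k], known$p1[k]))) {
      la <- lev(a, or[1]); lb <- lev(b, or[2])
      if (!is.na(la) && !is.na(lb)) {
        v <- mult * (la + lb) / 2
        if (is.na(best) || v > best) best <- v
      }
    }
    if (!is.na(best)) total <- sum(total, best, na.rm = TRUE)
  }
  total
}

# --- small fixture builders ---------------------------------------------

# nested toy clustering: two families with hand-chosen shared levels
toy_clustering <- function() {
  lv <- function(...) paste(c(...), collapse = ",")
  df <- data.frame(
    protein = c("A1", "A2", "A3", "B1", "B2"),
    family = c("FA", "FA", "FA", "FB", "FB"),
    levels = c(
      lv("f", "a", "a", "a", "a", "a", "a", "a", "a", "x", "x"),
      lv("f", "a", "a", "a", "a", "a", "a", "a", "a", "y", "y"),  # A1~A2 to 9
      lv("f", "b", "b", "b", "b", "b", "b", "b", "b", "b", "b"),
      lv("g", "c", "c", "c", "c", "c", "c", "u", "u", "u", "u"),
      lv("g", "c", "c", "c", "c", "c", "c", "v", "v", "v", "v")), # B1~B2 to 7
    stringsAsFactors = FALSE)
  family_clustering(df)
}

toy_dag <- function() {
  edges <- data.frame(
    child = c("A", "B", "C", "D", "E"),
    parent = c("root", "root", "A", "A", "B"),
    stringsAsFactors = FALSE)
  ann <- data.frame(
    protein = c("p1", "p1", "p2", "p3", "p4"),
    term = c("C", "E", "D", "C", "B"),
    stringsAsFactors = FALSE)
  annotation_dag(edges, ann)
}

# cross-validated MCC of one feature subset (internal training routine)
cv_mcc_for_test <- function(tab, feats) {
  spip:::cv_mcc(tab, feats, folds = 3L, seed = 2L)
}

small_params <- function(preset = "default", ...) {
  p <- bundle_params(preset)
  p <- utils::modifyList(p, list(n = 100L, m = 16L, n_bg_families = 40L,
                                 n_negatives = 30L, n_bg_known = 6L,
                                 n_seed_bg_known = 8L,
                                 fusions_per_genome = 8L,
                                 n_target_proteins = 80L))
  utils::modifyList(p, list(...))
}
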