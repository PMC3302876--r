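## Co-citation specificity scores over a physically-filtered literature
## interaction network. Direct (S1, "d-COCITE") and indirect (S2,
## "i-COCITE") association strengths between a reference set and each
## candidate protein, with a stickiness penalty for promiscuous nodes.

#' Build a co-citation network from a tagged edge list
#'
#' Edges carry a relation-class tag (e.g. `"physical"`); multi-edges are
#' collapsed to simple edges and self-loops dropped before any counting.
#'
#' @param edges Data frame with columns `p1`, `p2` and optionally
#'   `relation_class`.
#' @return An undirected `igraph` graph with edge attribute
#'   `relation_class` (when supplied).
#' @export
cocite_network <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("p1", "p2") %in% names(edges)))
  df <- data.frame(from = as.character(edges$p1), to = as.character(edges$p2),
                   stringsAsFactors = FALSE)
  if ("relation_class" %in% names(edges)) {
    df$relation_class <- as.character(edges$relation_class)
  }
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(relation_class = "first"))
}

#' Restrict a co-citation network to physical interactions
#'
#' Keeps only edges whose relation class is `"physical"` and drops nodes
#' left isolated; every edge must carry a tag.
#'
#' @param network Graph from [cocite_network()].
#' @return The filtered graph.
#' @export
filter_physical <- function(network) {
  cls <- igraph::edge_attr(network, "relation_class")
  if (is.null(cls) || anyNA(cls)) stop("every edge must carry a relation_class tag")
  g <- igraph::subgraph_from_edges(network,
                                   igraph::E(network)[cls == "physical"],
                                   delete.vertices = TRUE)
  g
}

#' Functional forms for the co-citation scores
#'
#' The precise algebraic combination of the citation counts is a pluggable
#' form; all registered forms satisfy the documented monotonicity contract
#' (increasing in specific counts, penalised by total degrees). The
#' default is `S1 = n_ri^2 / (N_r * N_i)` and
#' `S2 = n_rci^2 / (N_r2 * N_c * N_i)`.
#'
#' @param name Form name; currently `"default"`.
#' @return A list with functions `s1(n_ri, N_r, N_i)` and
#'   `s2(n_rci, N_r2, N_c, N_i)` and the form `name`.
#' @export
cocite_form <- function(name = "default") {
  switch(match.arg(name, "default"),
         default = list(
           name = "default",
           s1 = function(n_ri, N_r, N_i) {
             if (n_ri == 0) return(0)
             n_ri^2 / (N_r * N_i)
           },
           s2 = function(n_rci, N_r2, N_c, N_i) {
             if (n_rci == 0) return(0)
             n_rci^2 / (N_r2 * N_c * N_i)
           }))
}

cocite_counts_direct <- function(network, ref, i) {
  deg <- igraph::degree(network)
  nb <- names(igraph::neighbors(network, i))
  r <- intersect(nb, ref)
  list(n_ri = length(r), N_r = sum(deg[r]), N_i = unname(deg[i]))
}

cocite_counts_indirect <- function(network, ref, i) {
  deg <- igraph::degree(network)
  nb <- names(igraph::neighbors(network, i))
  n_rci <- 0L
  connectors <- character()
  reached <- character()
  for (c in nb) {
    rs <- setdiff(intersect(names(igraph::neighbors(network, c)), ref), i)
    if (length(rs)) {
      n_rci <- n_rci + length(rs)
      connectors <- c(connectors, c)
      reached <- union(reached, rs)
    }
  }
  list(n_rci = n_rci, N_r2 = sum(deg[reached]),
       N_c = sum(deg[unique(connectors)]), N_i = unname(deg[i]))
}

#' Direct co-citation specificity score (S1)
#'
#' Measures the strength of direct associations between protein `i` and a
#' reference set, normalised by the total connectivity of `i` and of the
#' reference members it touches, so that highly unspecific ("sticky")
#' proteins are penalised.
#'
#' @param network Physically filtered graph.
#' @param reference Reference set (or character vector of members).
#' @param i Protein identifier, present in the network.
#' @param form Functional form from [cocite_form()].
#' @return Non-negative score; `NA` (with attribute `reason`) for an
#'   isolated protein, which is distinct from a defined score of 0.
#' @export
s1_score <- function(network, reference, i, form = cocite_form()) {
  ref <- ref_members(reference)
  stopifnot(length(ref) > 0L)
  if (!i %in% igraph::V(network)$name) stop("protein not in network: ", i)
  ct <- cocite_counts_direct(network, ref, i)
  if (ct$N_i == 0) return(structure(NA_real_, reason = "isolated"))
  form$s1(ct$n_ri, ct$N_r, ct$N_i)
}

#' Indirect co-citation specificity score (S2)
#'
#' Counts length-2 paths from protein `i` through connector proteins into
#' the reference set, normalised by the degrees of the protein, the
#' connectors and the reference members reached.
#'
#' @inheritParams s1_score
#' @return Non-negative score, `NA` for an isolated protein.
#' @export
s2_score <- function(network, reference, i, form = cocite_form()) {
  ref <- ref_members(reference)
  stopifnot(length(ref) > 0L)
  if (!i %in% igraph::V(network)$name) stop("protein not in network: ", i)
  ct <- cocite_counts_indirect(network, ref, i)
  if (ct$N_i == 0) return(structure(NA_real_, reason = "isolated"))
  form$s2(ct$n_rci, ct$N_r2, ct$N_c, ct$N_i)
}

#' Score every non-reference protein by direct and indirect co-citation
#'
#' @inheritParams s1_score
#' @return A list with two per-target score tables, `d` (method
#'   `"d-COCITE"`) and `i` (method `"i-COCITE"`); reference members are
#'   excluded from the target lists.
#' @export
score_all_cocite <- function(network, reference, form = cocite_form()) {
  ref <- ref_members(reference)
  targets <- setdiff(igraph::V(network)$name, ref)
  s1 <- vapply(targets, function(t) as.numeric(s1_score(network, ref, t, form)),
               numeric(1))
  s2 <- vapply(targets, function(t) as.numeric(s2_score(network, ref, t, form)),
               numeric(1))
  out <- list(d = target_scores(targets, s1, "d-COCITE"),
              i = target_scores(targets, s2, "i-COCITE"))
  attr(out$d, "form") <- form$name
  attr(out$i, "form") <- form$name
  out
}
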