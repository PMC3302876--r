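## Evidence-graph construction (experimental "Knowledgegram" KG vs
## predicted "Predictogram" PG), degree and spindle-specificity
## statistics, and hidden-hub filtering: proteins with few experimentally
## known interactions but many predicted ones concentrated on the known
## module.

#' Build the predicted-interaction graph (PG) from channel pair p-values
#'
#' Takes every ab-initio channel's pair-level p-values and keeps pairs
#' passing the gate; pairs predicted by several channels merge into one
#' edge whose `sources` attribute unions the channel tags.
#'
#' @param channel_pairs Data frame with columns `p1`, `p2`, `channel`,
#'   `p`.
#' @param p_gate Inclusion threshold on the pair p-value (default 0.014).
#' @return Undirected simple `igraph` graph with edge attribute
#'   `sources`.
#' @export
build_pg <- function(channel_pairs, p_gate = 0.014) {
  stopifnot(is.data.frame(channel_pairs),
            all(c("p1", "p2", "channel", "p") %in% names(channel_pairs)))
  if (p_gate <= 0 || p_gate > 1) stop("p-value gate must be in (0, 1]")
  keep <- channel_pairs$p <= p_gate
  evidence_graph(channel_pairs[keep, c("p1", "p2", "channel")],
                 source_col = "channel", kind = "PG")
}

#' Build an evidence graph from tagged edge lists
#'
#' Used for the experimental-source KG; parallel edges from different
#' sources are merged with their source tags unioned.
#'
#' @param edges Data frame with columns `p1`, `p2` and a source column.
#' @param source_col Name of the source-tag column (default `"source"`).
#' @param kind Graph kind label, `"KG"` or `"PG"`.
#' @return Undirected simple `igraph` graph with edge attribute
#'   `sources`.
#' @export
evidence_graph <- function(edges, source_col = "source", kind = "KG") {
  df <- data.frame(from = as.character(edges$p1),
                   to = as.character(edges$p2),
                   sources = as.character(edges[[source_col]]),
                   stringsAsFactors = FALSE)
  df <- df[df$from != df$to, , drop = FALSE]
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = list(
    sources = function(x) paste(sort(unique(x)), collapse = ",")))
  igraph::graph_attr(g, "kind") <- kind
  g
}

#' Degree statistics of candidates in the KG and PG
#'
#' For each candidate, its degree in both graphs, the number of its PG
#' connections into the known-module set, and the fraction of its PG
#' degree those represent.
#'
#' @param candidates Character vector of candidate proteins.
#' @param kg,pg Evidence graphs.
#' @param spindle_set Known-module proteins.
#' @return Data frame `protein`, `kg_degree`, `pg_degree`,
#'   `spindle_degree_pg`, `spindle_fraction` (`NA` when the PG degree is
#'   zero).
#' @export
degree_stats <- function(candidates, kg, pg, spindle_set) {
  spindle <- ref_members(spindle_set)
  deg_in <- function(g, p) {
    if (p %in% igraph::V(g)$name) unname(igraph::degree(g, p)) else 0L
  }
  spin_deg <- function(g, p) {
    if (!p %in% igraph::V(g)$name) return(0L)
    length(intersect(names(igraph::neighbors(g, p)), spindle))
  }
  kg_d <- vapply(candidates, deg_in, numeric(1), g = kg)
  pg_d <- vapply(candidates, deg_in, numeric(1), g = pg)
  sp_d <- vapply(candidates, spin_deg, integer(1), g = pg)
  data.frame(protein = as.character(candidates),
             kg_degree = as.integer(kg_d), pg_degree = as.integer(pg_d),
             spindle_degree_pg = sp_d,
             spindle_fraction = ifelse(pg_d > 0, sp_d / pg_d, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select the top fraction of a ranked list
#'
#' @param ranking A `"spip_ranking"` (or data frame with `target`
#'   ordered best-first) or character vector.
#' @param fraction Fraction in `(0, 1]` (default 0.02); the top
#'   `floor(fraction * n)` targets are kept.
#' @return Character vector of candidates.
#' @export
select_top_fraction <- function(ranking, fraction = 0.02) {
  stopifnot(fraction > 0, fraction <= 1)
  targets <- if (is.data.frame(ranking)) ranking$target else
    as.character(ranking)
  head(targets, floor(fraction * length(targets)))
}

#' Filter and rank hidden hubs
#'
#' A hidden hub has a low experimentally known degree, at least
#' `min_ratio` times more predicted than known interactions
#' (`pg_degree >= min_ratio * max(kg_degree, 1)`), and a high fraction of
#' its predicted connections into the known module. Survivors are ranked
#' by predicted degree, then module specificity, then identifier.
#'
#' @param records Data frame from [degree_stats()].
#' @param min_ratio Predicted-to-known degree ratio (default 5).
#' @param max_kg_degree Maximum known degree (default 5).
#' @param min_spindle_fraction Minimum module-specific fraction of the
#'   predicted degree (default 0.5).
#' @return The qualifying records, ranked, with a `rank` column; the
#'   thresholds are recorded as attributes.
#' @export
hidden_hub_rank <- function(records, min_ratio = 5, max_kg_degree = 5,
                            min_spindle_fraction = 0.5) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    out <- cbind(records, rank = integer())
  } else {
    keep <- records$kg_degree <= max_kg_degree &
      records$pg_degree >= min_ratio * pmax(records$kg_degree, 1) &
      !is.na(records$spindle_fraction) &
      records$spindle_fraction >= min_spindle_fraction
    out <- records[keep, , drop = FALSE]
    out <- out[order(-out$pg_degree, -out$spindle_fraction, out$protein), ,
               drop = FALSE]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
  }
  attr(out, "thresholds") <- c(min_ratio = min_ratio,
                               max_kg_degree = max_kg_degree,
                               min_spindle_fraction = min_spindle_fraction)
  out
}
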