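## Resnik semantic similarity (GOSS) between proteins over an annotation
## ontology: information content of the most informative common ancestor,
## aggregated across the two proteins' annotation sets.

#' Build an annotation DAG with cumulative term frequencies
#'
#' The ontology is a rooted acyclic graph of is-a edges (child -> parent).
#' Each term's cumulative probability `p(c)` is the fraction of annotated
#' proteins annotated to the term or any of its descendants, so `p` is
#' non-decreasing from child to parent and `p(root) = 1`.
#'
#' @param edges Data frame with columns `child`, `parent`.
#' @param annotations Data frame with columns `protein`, `term`.
#' @return Object of class `"annotation_dag"` with per-term ancestor
#'   sets, probabilities and information contents.
#' @export
annotation_dag <- function(edges, annotations) {
  stopifnot(is.data.frame(edges), all(c("child", "parent") %in% names(edges)))
  stopifnot(is.data.frame(annotations),
            all(c("protein", "term") %in% names(annotations)))
  child <- as.character(edges$child)
  parent <- as.character(edges$parent)
  terms <- union(child, parent)
  roots <- setdiff(parent, child)
  if (length(roots) != 1L) {
    stop("DAG must have exactly one root, found: ",
         paste(roots, collapse = ", "))
  }
  parents_of <- split(parent, factor(child, levels = terms))
  # ancestors (including self), memoised in dependency order
  anc <- setNames(vector("list", length(terms)), terms)
  get_anc <- function(t, seen = character()) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    if (t %in% seen) stop("cycle detected at term ", t)
    ps <- parents_of[[t]]
    res <- t
    for (p in ps) res <- union(res, get_anc(p, c(seen, t)))
    anc[[t]] <<- res
    res
  }
  for (t in terms) get_anc(t)
  ann <- split(as.character(annotations$term),
               as.character(annotations$protein))
  ann <- lapply(ann, unique)
  bad <- setdiff(unlist(ann), terms)
  if (length(bad)) stop("annotation to unknown term: ", bad[1L])
  n_prot <- length(ann)
  if (n_prot == 0L) stop("no annotated proteins")
  # cumulative counts: protein counts toward every ancestor of its terms
  counts <- setNames(integer(length(terms)), terms)
  for (ts in ann) {
    up <- unique(unlist(anc[ts], use.names = FALSE))
    counts[up] <- counts[up] + 1L
  }
  p <- counts / n_prot
  ic <- ifelse(p > 0, -log(p), NA_real_)
  structure(list(terms = terms, root = roots, ancestors = anc,
                 p = p, ic = setNames(ic, terms), annotations = ann,
                 n_annotated = n_prot),
            class = "annotation_dag")
}

#' Information content of a term
#'
#' `IC(c) = -ln p(c)` with the cumulative annotation probability `p`;
#' the root has IC 0 and unannotated terms (`p = 0`) are undefined.
#'
#' @param dag An `"annotation_dag"`.
#' @param term Term identifier.
#' @return Non-negative IC in nats, or `NA` for an unannotated term.
#' @export
information_content <- function(dag, term) {
  stopifnot(inherits(dag, "annotation_dag"))
  if (!term %in% dag$terms) stop("unknown term: ", term)
  unname(dag$ic[term])
}

#' Resnik similarity of two terms
#'
#' Information content of the most informative common ancestor (MICA);
#' zero when the terms share only the root.
#'
#' @param dag An `"annotation_dag"`.
#' @param t1,t2 Term identifiers.
#' @return Non-negative similarity in nats.
#' @export
resnik_term_sim <- function(dag, t1, t2) {
  stopifnot(inherits(dag, "annotation_dag"))
  if (!t1 %in% dag$terms) stop("unknown term: ", t1)
  if (!t2 %in% dag$terms) stop("unknown term: ", t2)
  common <- intersect(dag$ancestors[[t1]], dag$ancestors[[t2]])
  ics <- dag$ic[common]
  ics <- ics[!is.na(ics)]
  if (!length(ics)) return(0)
  max(ics)
}

#' Semantic similarity of two proteins
#'
#' Aggregates pairwise Resnik term similarities across the two proteins'
#' annotation sets; the default aggregation is the maximum, consistent
#' with the best-score collapse used platform-wide. `"bma"` gives the
#' best-match average.
#'
#' @param dag An `"annotation_dag"`.
#' @param p1,p2 Protein identifiers.
#' @param aggregation `"max"` (default) or `"bma"`.
#' @return Similarity in nats, or `NA` if either protein is unannotated.
#' @export
goss_protein_sim <- function(dag, p1, p2, aggregation = c("max", "bma")) {
  aggregation <- match.arg(aggregation)
  a <- dag$annotations[[p1]]
  b <- dag$annotations[[p2]]
  if (is.null(a) || is.null(b)) return(NA_real_)
  m <- outer(a, b, Vectorize(function(x, y) resnik_term_sim(dag, x, y)))
  if (aggregation == "max") return(max(m))
  (mean(apply(m, 1L, max)) + mean(apply(m, 2L, max))) / 2
}

#' Score all targets by semantic similarity to a reference set
#'
#' @param dag An `"annotation_dag"`.
#' @param reference Reference protein set.
#' @param targets Candidates; defaults to all annotated non-reference
#'   proteins.
#' @param aggregation Passed to [goss_protein_sim()].
#' @return Per-target best-score table (method `"GOSS"`).
#' @export
goss_score_all <- function(dag, reference, targets = NULL,
                           aggregation = "max") {
  ref <- intersect(ref_members(reference), names(dag$annotations))
  if (is.null(targets)) targets <- setdiff(names(dag$annotations), ref)
  targets <- intersect(targets, names(dag$annotations))
  if (!length(ref) || !length(targets)) {
    return(target_scores(character(), numeric(), "GOSS"))
  }
  # max aggregation: the best term pair across all reference members is
  # max over the union of reference terms, so precompute per-term bests
  ref_terms <- unique(unlist(dag$annotations[ref], use.names = FALSE))
  sim_to_ref <- function(term) {
    max(vapply(ref_terms, function(rt) resnik_term_sim(dag, term, rt),
               numeric(1)))
  }
  all_terms <- unique(unlist(dag$annotations[targets], use.names = FALSE))
  best_by_term <- vapply(setNames(nm = all_terms), sim_to_ref, numeric(1))
  sc <- vapply(targets, function(p) {
    if (aggregation == "max") {
      max(best_by_term[dag$annotations[[p]]])
    } else {
      best <- vapply(ref, function(r)
        goss_protein_sim(dag, p, r, aggregation), numeric(1))
      max(best)
    }
  }, numeric(1))
  target_scores(targets, sc, "GOSS")
}
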