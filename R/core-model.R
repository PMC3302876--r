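## Shared domain types: protein registry, reference sets, scored pairs and
## the bait-target -> per-target best-score collapse used by every pairwise
## evidence channel.

#' Create a reference set of known positives
#'
#' A reference set is a named collection of protein identifiers (for
#' example the curated set used to seed the pairwise scorers, or an
#' independent holdout used for benchmarking). Identifiers are opaque
#' tokens compared by exact string equality.
#'
#' @param name Label for the set (e.g. `"SEED"`, `"EXPERT"`).
#' @param members Character vector of protein identifiers; duplicates are
#'   removed.
#' @param registry Optional character vector of all proteins in the
#'   proteome; when supplied, members outside the registry are an error.
#' @return An object of class `"reference_set"`.
#' @export
reference_set <- function(name, members, registry = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  members <- unique(as.character(members))
  if (any(!nzchar(members)) || anyNA(members)) {
    stop("reference set members must be non-empty identifiers")
  }
  if (!is.null(registry)) {
    bad <- setdiff(members, registry)
    if (length(bad)) {
      stop("reference set members not in registry: ",
           paste(head(bad, 5L), collapse = ", "))
    }
  }
  structure(list(name = name, members = members), class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("Reference set '%s': %d proteins\n", x$name, length(x$members)))
  invisible(x)
}

ref_members <- function(x) {
  if (inherits(x, "reference_set")) x$members else unique(as.character(x))
}

#' Combine two reference sets by union
#'
#' Combines two curated sets into one, reporting the overlap. Used, for
#' instance, to merge a seed set with an independent expert set into the
#' full list of known positives before network analysis.
#'
#' @param a,b Objects of class `"reference_set"`.
#' @param registry Optional registry to validate against.
#' @param name Name for the combined set.
#' @return A `"reference_set"` whose `overlap` attribute records the size
#'   of the intersection.
#' @export
combine_reference_sets <- function(a, b, registry = NULL,
                                   name = paste(a$name, b$name, sep = "+")) {
  stopifnot(inherits(a, "reference_set"), inherits(b, "reference_set"))
  if (!is.null(registry)) {
    bad <- setdiff(c(a$members, b$members), registry)
    if (length(bad)) {
      stop("member outside registry: ", paste(head(bad, 5L), collapse = ", "))
    }
  }
  out <- reference_set(name, union(a$members, b$members))
  attr(out, "overlap") <- length(intersect(a$members, b$members))
  out
}

#' Construct a table of bait-target scored pairs
#'
#' @param bait,target Character vectors of protein identifiers.
#' @param score Numeric scores, finite.
#' @param method Single method tag attached to every pair.
#' @return A data frame with columns `bait`, `target`, `score`, `method`.
#' @export
scored_pairs <- function(bait, target, score, method) {
  stopifnot(length(bait) == length(target), length(bait) == length(score),
            is.character(method), length(method) == 1L)
  if (length(score) && any(!is.finite(score))) stop("scores must be finite")
  data.frame(bait = as.character(bait), target = as.character(target),
             score = as.numeric(score),
             method = rep_len(method, length(bait)),
             stringsAsFactors = FALSE)
}

#' Collapse bait-target pairs to one best score per target
#'
#' Pairwise methods can retrieve the same target with several baits at
#' different scores; each target is kept once with the best score over all
#' pairs in which it was detected. Targets with no pair are absent (not
#' zero-filled).
#'
#' @param pairs Data frame as from [scored_pairs()]; all rows must carry
#'   the same method tag.
#' @param higher_better Score orientation: if `TRUE` (default) the maximum
#'   is kept, otherwise the minimum.
#' @return A data frame (`target`, `score`, `n_baits`) with attributes
#'   `method` and `higher_better`; `n_baits` counts the contributing pairs
#'   for diagnostics.
#' @export
collapse_pairs <- function(pairs, higher_better = TRUE) {
  stopifnot(is.data.frame(pairs),
            all(c("bait", "target", "score") %in% names(pairs)))
  if (nrow(pairs) == 0L) {
    out <- data.frame(target = character(), score = numeric(),
                      n_baits = integer(), stringsAsFactors = FALSE)
  } else {
    if ("method" %in% names(pairs) && length(unique(pairs$method)) > 1L) {
      stop("mixed method tags in pair list: ",
           paste(unique(pairs$method), collapse = ", "))
    }
    if (any(!is.finite(pairs$score))) stop("scores must be finite")
    pick <- if (higher_better) max else min
    grp <- split(pairs$score, pairs$target)
    out <- data.frame(target = names(grp),
                      score = vapply(grp, pick, numeric(1)),
                      n_baits = lengths(grp),
                      stringsAsFactors = FALSE, row.names = NULL)
    out <- out[order(out$target), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "method") <- if ("method" %in% names(pairs) && nrow(pairs))
    pairs$method[1L] else NA_character_
  attr(out, "higher_better") <- higher_better
  out
}

## internal: a bare per-target score list (already collapsed)
target_scores <- function(target, score, method, higher_better = TRUE) {
  keep <- !is.na(score)
  out <- data.frame(target = as.character(target)[keep],
                    score = as.numeric(score)[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$target), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "method") <- method
  attr(out, "higher_better") <- higher_better
  out
}
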