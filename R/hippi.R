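## Homology-inherited protein-protein interaction (hiPPI) scoring.
## Protein families are sub-clustered at 11 nested sequence-identity
## levels ("S-levels", 1-11); known interactions are inherited to family
## homologues and scored by the closeness of the inheriting proteins to
## the evidence pair, plus a halving bonus series for extra experimental
## evidence types and species.

#' Build a family clustering with nested S-level clusters
#'
#' @param df Data frame with columns `protein`, `family` and `levels`
#'   (comma-separated cluster identifiers for S-levels 1..11, coarsest
#'   first).
#' @param n_levels Number of S-levels (default 11).
#' @return Object of class `"family_clustering"`.
#' @export
family_clustering <- function(df, n_levels = 11L) {
  stopifnot(is.data.frame(df),
            all(c("protein", "family", "levels") %in% names(df)))
  prot <- as.character(df$protein)
  if (anyDuplicated(prot)) {
    stop("duplicated protein in clustering: ", prot[duplicated(prot)][1L])
  }
  lv <- strsplit(as.character(df$levels), ",", fixed = TRUE)
  if (any(lengths(lv) != n_levels)) {
    stop("every protein needs exactly ", n_levels, " cluster identifiers")
  }
  m <- do.call(rbind, lv)
  rownames(m) <- prot
  # nesting check: two proteins sharing a cluster at level L must share
  # clusters at all coarser levels
  for (L in 2:n_levels) {
    map <- tapply(m[, L - 1L], m[, L], function(x) length(unique(x)))
    if (any(map > 1L)) stop("cluster nesting violated at S-level ", L)
  }
  structure(list(protein = prot, family = as.character(df$family),
                 levels = m, n_levels = as.integer(n_levels)),
            class = "family_clustering")
}

#' Highest shared S-level of two proteins
#'
#' The evolutionary closeness of an inheriting protein to the protein
#' carrying the known interaction, measured as the deepest
#' sequence-identity cluster the two share.
#'
#' @param clustering A `"family_clustering"`.
#' @param a,b Protein identifiers.
#' @return Integer S-level in 1..11; `NA` when the proteins belong to
#'   different families (no inheritance possible). A protein with itself
#'   shares the top cluster.
#' @export
slevel_of <- function(clustering, a, b) {
  stopifnot(inherits(clustering, "family_clustering"))
  ia <- match(a, clustering$protein)
  ib <- match(b, clustering$protein)
  if (is.na(ia) || is.na(ib)) stop("protein not in clustering")
  if (clustering$family[ia] != clustering$family[ib]) return(NA_integer_)
  if (ia == ib) return(clustering$n_levels)
  eq <- clustering$levels[ia, ] == clustering$levels[ib, ]
  if (!any(eq)) return(NA_integer_)
  max(which(eq))
}

#' Base inheritance score from two S-levels
#'
#' Arithmetic mean of the S-levels at which the two inheriting proteins
#' sit relative to the evidence pair, so interactions inherited from
#' distant homologues contribute less than those from close ones.
#'
#' @param level_a,level_b Integer S-levels in 1..11.
#' @return The mean of the two levels.
#' @export
base_inherit_score <- function(level_a, level_b) {
  stopifnot(all(level_a >= 1 & level_a <= 11),
            all(level_b >= 1 & level_b <= 11))
  (level_a + level_b) / 2
}

#' Multi-evidence bonus: halving series on top of a base score
#'
#' Each extra experimental evidence type or extra species beyond the
#' first adds half as much as the previous addition: the first extra unit
#' adds `base/2`, the next `base/4`, and so on. Extras are pooled with
#' evidence types counted before species.
#'
#' @param base Base inheritance score.
#' @param n_evidence_types Number of independent experimental evidence
#'   types (>= 1).
#' @param n_species Number of species the interaction is seen in (>= 1).
#' @return The total score, `base` plus the bonus series.
#' @export
evidence_bonus <- function(base, n_evidence_types, n_species) {
  stopifnot(n_evidence_types >= 1, n_species >= 1)
  extras <- (n_evidence_types - 1L) + (n_species - 1L)
  if (extras == 0L) return(base)
  base + base * sum(0.5 ^ seq_len(extras))
}

#' hiPPI score for a candidate protein pair
#'
#' Sum over all supporting known interactions of the base inheritance
#' score plus the multi-evidence bonus; each distinct known pair
#' contributes through its own S-levels.
#'
#' @param a,b Candidate pair of proteins.
#' @param clustering A `"family_clustering"`.
#' @param known Data frame of known interactions with columns `p1`, `p2`,
#'   `evidence_types` (comma-separated), `species` (comma-separated).
#' @return Total score, or `NA` when no known interaction supports the
#'   pair.
#' @export
hippi_pair_score <- function(a, b, clustering, known) {
  stopifnot(is.data.frame(known),
            all(c("p1", "p2", "evidence_types", "species") %in% names(known)))
  total <- NA_real_
  in_cl <- function(p) p %in% clustering$protein
  if (!in_cl(a) || !in_cl(b)) return(NA_real_)
  for (k in seq_len(nrow(known))) {
    p1 <- known$p1[k]; p2 <- known$p2[k]
    if (!in_cl(p1) || !in_cl(p2)) next
    n_ev <- length(strsplit(as.character(known$evidence_types[k]), ",")[[1]])
    n_sp <- length(strsplit(as.character(known$species[k]), ",")[[1]])
    contrib <- NA_real_
    # two possible orientations of homology support; keep the better one
    for (or in list(c(p1, p2), c(p2, p1))) {
      la <- slevel_of(clustering, a, or[1L])
      lb <- slevel_of(clustering, b, or[2L])
      if (!is.na(la) && !is.na(lb)) {
        v <- evidence_bonus(base_inherit_score(la, lb), n_ev, n_sp)
        if (is.na(contrib) || v > contrib) contrib <- v
      }
    }
    if (!is.na(contrib)) total <- sum(total, contrib, na.rm = TRUE)
  }
  total
}

## internal: all (bait, target) hiPPI scores as a pair table; vectorised
## over family blocks so genome-wide scoring stays fast. Produces the
## same scores as per-pair hippi_pair_score calls.
hippi_pairs <- function(clustering, known, baits, targets) {
  fam_of <- setNames(clustering$family, clustering$protein)
  lv <- clustering$levels
  nb <- length(baits)
  nt <- length(targets)
  if (nb == 0L || nt == 0L || nrow(known) == 0L) {
    return(scored_pairs(character(), character(), numeric(), "hiPPI"))
  }
  total <- base::matrix(0, nb, nt, dimnames = list(baits, targets))
  has <- base::matrix(FALSE, nb, nt)
  shared_level <- function(xs, e) {
    # nested clusters: equal levels form a prefix, so the deepest shared
    # level is the count of equal entries
    rowSums(lv[xs, , drop = FALSE] ==
              base::matrix(lv[e, ], length(xs), ncol(lv), byrow = TRUE))
  }
  for (k in seq_len(nrow(known))) {
    p1 <- known$p1[k]; p2 <- known$p2[k]
    if (!p1 %in% clustering$protein || !p2 %in% clustering$protein) next
    n_ev <- length(strsplit(as.character(known$evidence_types[k]), ",")[[1]])
    n_sp <- length(strsplit(as.character(known$species[k]), ",")[[1]])
    extras <- (n_ev - 1L) + (n_sp - 1L)
    mult <- 1 + if (extras > 0L) sum(0.5 ^ seq_len(extras)) else 0
    contrib <- base::matrix(NA_real_, nb, nt)
    for (or in list(c(p1, p2), c(p2, p1))) {
      bs <- which(fam_of[baits] == fam_of[[or[1L]]])
      ts <- which(fam_of[targets] == fam_of[[or[2L]]])
      if (!length(bs) || !length(ts)) next
      la <- shared_level(baits[bs], or[1L])
      lb <- shared_level(targets[ts], or[2L])
      ok <- la >= 1
      okb <- lb >= 1
      if (!any(ok) || !any(okb)) next
      block <- mult * outer(la[ok], lb[okb], `+`) / 2
      cur <- contrib[bs[ok], ts[okb], drop = FALSE]
      contrib[bs[ok], ts[okb]] <- pmax(cur, block, na.rm = TRUE)
    }
    found <- !is.na(contrib)
    total[found] <- total[found] + contrib[found]
    has <- has | found
  }
  same <- outer(baits, targets, `==`)
  has[same] <- FALSE
  idx <- which(has, arr.ind = TRUE)
  scored_pairs(baits[idx[, 1L]], targets[idx[, 2L]], total[has], "hiPPI")
}

#' Score all bait-target pairs with hiPPI and collapse per target
#'
#' @param clustering A `"family_clustering"`.
#' @param known Known-interaction data frame (see [hippi_pair_score()]).
#' @param baits Reference proteins.
#' @param targets Candidates; defaults to all clustered non-bait proteins.
#' @return Per-target best-score table (method `"hiPPI"`); targets with
#'   no supporting interaction are absent.
#' @export
hippi_score_all <- function(clustering, known, baits, targets = NULL) {
  baits <- ref_members(baits)
  if (is.null(targets)) targets <- setdiff(clustering$protein, baits)
  baits <- intersect(baits, clustering$protein)
  targets <- intersect(targets, clustering$protein)
  collapse_pairs(hippi_pairs(clustering, known, baits, targets),
                 higher_better = TRUE)
}
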