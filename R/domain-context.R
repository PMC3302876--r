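## Domain-context evidence: CODA domain-fusion (Rosetta-stone) association
## scores between protein pairs, and DORA per-domain over-representation
## scores for single proteins.

#' Build a multi-genome domain-architecture table
#'
#' @param df Data frame with columns `genome`, `protein` and
#'   `superfamilies` (comma-separated superfamily identifiers, ordered as
#'   they occur along the protein; repeats allowed).
#' @return Object of class `"domain_archs"`: per genome, a named list of
#'   character vectors of superfamily occurrences.
#' @export
domain_archs <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("genome", "protein", "superfamilies") %in% names(df)))
  sfs <- strsplit(as.character(df$superfamilies), ",", fixed = TRUE)
  if (any(lengths(sfs) == 0L)) stop("empty architecture row")
  out <- list()
  for (g in unique(as.character(df$genome))) {
    idx <- which(df$genome == g)
    prot <- as.character(df$protein[idx])
    if (anyDuplicated(prot)) {
      stop("duplicated protein in genome ", g, ": ",
           prot[duplicated(prot)][1L])
    }
    out[[g]] <- setNames(sfs[idx], prot)
  }
  structure(out, class = "domain_archs")
}

#' Superfamily occurrence frequencies within one genome
#'
#' Counts every occurrence (repeats included) of each superfamily across
#' all architectures of the genome.
#'
#' @param archs A `"domain_archs"` object.
#' @param genome Genome tag.
#' @return Named integer vector of counts.
#' @export
genome_domain_freqs <- function(archs, genome) {
  stopifnot(inherits(archs, "domain_archs"))
  if (!genome %in% names(archs)) stop("unknown genome: ", genome)
  tab <- table(unlist(archs[[genome]], use.names = FALSE))
  setNames(as.integer(tab), names(tab))
}

#' Enumerate the candidate domain pairs between two architectures
#'
#' All distinct cross pairs `(a, b)` with `a` from the first protein and
#' `b` from the second, requiring `a != b`. Pairs are returned in
#' canonical (sorted) order since fusion evidence is orientation-free.
#'
#' @param dp,dq Character vectors of superfamily occurrences.
#' @return Data frame with columns `a`, `b` (possibly zero rows).
#' @export
domain_pairs <- function(dp, dq) {
  a <- unique(as.character(dp))
  b <- unique(as.character(dq))
  grid <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
  grid <- grid[grid$a != grid$b, , drop = FALSE]
  if (nrow(grid)) {
    swap <- grid$a > grid$b
    tmp <- grid$a[swap]
    grid$a[swap] <- grid$b[swap]
    grid$b[swap] <- tmp
    grid <- unique(grid)
  }
  rownames(grid) <- NULL
  grid
}

#' Functional form for the per-domain-pair fusion score
#'
#' The algebraic combination of the genome counts is pluggable; the
#' default rewards corroboration by more fusion genomes and rarity of both
#' superfamilies: `s_ab = max_t |T| / (f_g_a * f_g_b * f_t_a * f_t_b)`.
#'
#' @param name Form name; currently `"default"`.
#' @return List with `name` and function
#'   `score(n_T, f_g_a, f_g_b, f_t_a, f_t_b)`.
#' @export
coda_form <- function(name = "default") {
  switch(match.arg(name, "default"),
         default = list(
           name = "default",
           score = function(n_T, f_g_a, f_g_b, f_t_a, f_t_b) {
             n_T / (f_g_a * f_g_b * f_t_a * f_t_b)
           }))
}

#' Index fusion evidence across target genomes
#'
#' For every canonical superfamily pair fused within a single protein of a
#' non-query genome, records the set of genomes carrying such a fusion
#' protein.
#'
#' @param archs A `"domain_archs"` object.
#' @param query_genome Genome whose protein pairs are being scored.
#' @return Named list: `"a|b"` -> character vector of fusion genomes.
#' @export
coda_fusion_index <- function(archs, query_genome) {
  stopifnot(inherits(archs, "domain_archs"))
  idx <- list()
  for (t in setdiff(names(archs), query_genome)) {
    for (arch in archs[[t]]) {
      u <- unique(arch)
      if (length(u) < 2L) next
      cmb <- utils::combn(sort(u), 2L)
      keys <- paste(cmb[1L, ], cmb[2L, ], sep = "|")
      for (k in keys) idx[[k]] <- union(idx[[k]], t)
    }
  }
  idx
}

#' CODA fusion score for a pair of proteins in the query genome
#'
#' For each candidate domain pair the fusion score is maximised over all
#' genomes containing a fusion protein; the pair score is the best score
#' over all candidate domain pairs. Protein pairs sharing any superfamily
#' are excluded entirely.
#'
#' @param p,q Protein identifiers in the query genome.
#' @param archs A `"domain_archs"` object.
#' @param query_genome Query genome tag.
#' @param form Form from [coda_form()].
#' @param index Optional precomputed [coda_fusion_index()].
#' @param freqs Optional precomputed list of per-genome
#'   [genome_domain_freqs()].
#' @return Numeric score, or `NA` when no fusion evidence exists or the
#'   pair shares a superfamily.
#' @export
coda_pair_score <- function(p, q, archs, query_genome, form = coda_form(),
                            index = NULL, freqs = NULL) {
  stopifnot(inherits(archs, "domain_archs"))
  qa <- archs[[query_genome]]
  if (is.null(qa[[p]])) stop("protein absent from query genome: ", p)
  if (is.null(qa[[q]])) stop("protein absent from query genome: ", q)
  if (length(intersect(qa[[p]], qa[[q]]))) return(NA_real_)
  J <- domain_pairs(qa[[p]], qa[[q]])
  if (nrow(J) == 0L) return(NA_real_)
  if (is.null(index)) index <- coda_fusion_index(archs, query_genome)
  if (is.null(freqs)) {
    freqs <- lapply(setNames(nm = names(archs)),
                    function(g) genome_domain_freqs(archs, g))
  }
  fg <- freqs[[query_genome]]
  best <- NA_real_
  for (k in seq_len(nrow(J))) {
    a <- J$a[k]; b <- J$b[k]
    genomes <- index[[paste(a, b, sep = "|")]]
    if (is.null(genomes)) next
    n_T <- length(genomes)
    s_ab <- max(vapply(genomes, function(t) {
      form$score(n_T, fg[[a]], fg[[b]], freqs[[t]][[a]], freqs[[t]][[b]])
    }, numeric(1)))
    if (is.na(best) || s_ab > best) best <- s_ab
  }
  best
}

#' Score all bait-target pairs with CODA and collapse per target
#'
#' @param archs A `"domain_archs"` object.
#' @param query_genome Query genome tag.
#' @param baits Reference proteins acting as baits.
#' @param targets Candidate proteins; defaults to all non-bait proteins of
#'   the query genome.
#' @param method Method tag for the resulting channel (e.g. `"CODAcath"`).
#' @param form Form from [coda_form()].
#' @return Per-target best-score table (see [collapse_pairs()]).
#' @export
coda_score_all <- function(archs, query_genome, baits, targets = NULL,
                           method = "CODA", form = coda_form()) {
  baits <- ref_members(baits)
  qa <- archs[[query_genome]]
  if (is.null(targets)) targets <- setdiff(names(qa), baits)
  baits <- intersect(baits, names(qa))
  targets <- intersect(targets, names(qa))
  index <- coda_fusion_index(archs, query_genome)
  freqs <- lapply(setNames(nm = names(archs)),
                  function(g) genome_domain_freqs(archs, g))
  rows <- list()
  for (b in baits) {
    sc <- vapply(targets, function(t) {
      if (t == b) return(NA_real_)
      coda_pair_score(b, t, archs, query_genome, form, index, freqs)
    }, numeric(1))
    keep <- !is.na(sc)
    if (any(keep)) {
      rows[[b]] <- data.frame(bait = b, target = targets[keep],
                              score = sc[keep], method = method,
                              stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    scored_pairs(character(), character(), numeric(), method)
  out <- collapse_pairs(pairs, higher_better = TRUE)
  attr(out, "form") <- form$name
  out
}

#' DORA over-representation score for one domain family
#'
#' Ratio of the relative frequency of a family in the target (reference)
#' set of proteins to its relative frequency in the whole genome:
#' `Cij = (Ft/Nt) / (Fb/Nb)`.
#'
#' @param Ft Family count in the target set.
#' @param Nt Total domain count in the target set.
#' @param Fb Family count in the genome background.
#' @param Nb Total domain count in the genome background.
#' @return Non-negative ratio; `NA` when the family is absent from the
#'   background (`Fb = 0`), vectorised over `Ft`/`Fb`.
#' @export
dora_score <- function(Ft, Nt, Fb, Nb) {
  stopifnot(all(Nt > 0), all(Nb > 0))
  if (any(Ft > Fb, na.rm = TRUE)) stop("family count in target exceeds background")
  out <- (Ft / Nt) / (Fb / Nb)
  out[Fb == 0] <- NA_real_
  out
}

#' Per-family DORA table for a genome and a target protein set
#'
#' @param archs A `"domain_archs"` object.
#' @param genome Genome tag.
#' @param target_set Proteins whose domains define the target group.
#' @return Data frame `family`, `Ft`, `Nt`, `Fb`, `Nb`, `Cij`.
#' @export
dora_table <- function(archs, genome, target_set) {
  target_set <- ref_members(target_set)
  qa <- archs[[genome]]
  all_dom <- unlist(qa, use.names = FALSE)
  tgt_dom <- unlist(qa[intersect(target_set, names(qa))], use.names = FALSE)
  Nb <- length(all_dom)
  Nt <- length(tgt_dom)
  if (Nt == 0L) stop("target set contributes no domains")
  fb <- table(all_dom)
  ft <- table(factor(tgt_dom, levels = names(fb)))
  out <- data.frame(family = names(fb), Ft = as.integer(ft), Nt = Nt,
                    Fb = as.integer(fb), Nb = Nb, stringsAsFactors = FALSE)
  out$Cij <- dora_score(out$Ft, out$Nt, out$Fb, out$Nb)
  out
}

#' Best DORA score per protein
#'
#' When a protein contains several annotated families the prediction with
#' the best score is selected.
#'
#' @param archs A `"domain_archs"` object.
#' @param genome Genome tag.
#' @param target_set Reference proteins defining the target group.
#' @param targets Proteins to score; defaults to all non-reference
#'   proteins of the genome.
#' @return Per-target score table (method `"DORA"`); proteins with no
#'   scorable family are absent.
#' @export
dora_protein_scores <- function(archs, genome, target_set, targets = NULL) {
  target_set <- ref_members(target_set)
  qa <- archs[[genome]]
  if (is.null(targets)) targets <- setdiff(names(qa), target_set)
  tab <- dora_table(archs, genome, target_set)
  cij <- setNames(tab$Cij, tab$family)
  sc <- vapply(targets, function(p) {
    fams <- unique(qa[[p]])
    v <- cij[fams]
    v <- v[!is.na(v)]
    if (length(v)) max(v) else NA_real_
  }, numeric(1))
  target_scores(targets, sc, "DORA")
}
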