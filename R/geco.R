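## Gene-expression correlation (GECO): Pearson correlation of expression
## profiles between reference and candidate genes over a genes x
## conditions matrix with bounded missingness.

#' Pearson correlation of two expression profiles with missingness gates
#'
#' Computes the Pearson correlation over conditions observed in both
#' profiles. No score is returned when either profile exceeds the allowed
#' number of missing values, the common support is below 3 conditions, or
#' either profile has zero variance on the common support.
#'
#' @param matrix Numeric genes x conditions matrix with `NA` for missing;
#'   rownames are gene identifiers.
#' @param g1,g2 Gene identifiers.
#' @param max_missing Maximum missing values allowed per full profile
#'   (default 5).
#' @return Correlation in `[-1, 1]`, or `NA` with a `reason` attribute
#'   (`"missing_gate"`, `"support"` or `"zero_variance"`).
#' @export
geco_pair <- function(matrix, g1, g2, max_missing = 5L) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  if (!g1 %in% rownames(matrix)) stop("gene not in matrix: ", g1)
  if (!g2 %in% rownames(matrix)) stop("gene not in matrix: ", g2)
  x <- matrix[g1, ]
  y <- matrix[g2, ]
  if (sum(is.na(x)) > max_missing || sum(is.na(y)) > max_missing) {
    return(structure(NA_real_, reason = "missing_gate"))
  }
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) return(structure(NA_real_, reason = "support"))
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    return(structure(NA_real_, reason = "zero_variance"))
  }
  cor(x[ok], y[ok])
}

#' Score all targets by best correlation with any reference gene
#'
#' Every (reference, target) pair passing the missingness gates is scored
#' by Pearson correlation; per target the signed maximum (most positive
#' correlation) is kept.
#'
#' @param matrix Genes x conditions matrix with `NA` for missing.
#' @param reference Reference gene set.
#' @param max_missing Per-profile missing-value gate (default 5).
#' @param targets Candidate genes; defaults to all non-reference rows.
#' @return Per-target best-score table (method `"GECO"`).
#' @export
score_all_geco <- function(matrix, reference, max_missing = 5L,
                           targets = NULL) {
  ref <- intersect(ref_members(reference), rownames(matrix))
  if (is.null(targets)) targets <- setdiff(rownames(matrix), ref)
  targets <- intersect(targets, rownames(matrix))
  miss <- rowSums(is.na(matrix))
  ref_ok <- ref[miss[ref] <= max_missing]
  tgt_ok <- targets[miss[targets] <= max_missing]
  if (!length(ref_ok) || !length(tgt_ok)) {
    return(target_scores(character(), numeric(), "GECO"))
  }
  X <- t(matrix[ref_ok, , drop = FALSE])
  Y <- t(matrix[tgt_ok, , drop = FALSE])
  suppressWarnings(cc <- cor(X, Y, use = "pairwise.complete.obs"))
  # enforce minimum common support of 3 conditions
  supp <- crossprod(!is.na(X), !is.na(Y))
  cc[supp < 3L] <- NA
  best <- apply(cc, 2L, function(v) if (all(is.na(v))) NA_real_ else
    max(v, na.rm = TRUE))
  target_scores(tgt_ok, best, "GECO")
}
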