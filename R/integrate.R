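## Score -> p-value conversion, two-stage Fisher combination into the
## integrated platform score, calibration diagnostics, and the normalised
## mutual-information distance used to check channel independence.

#' Empirical right-tail p-values for a channel's scores
#'
#' Add-one empirical estimator against the channel's own cumulative score
#' distribution: `p(s) = (1 + #\{scores >= s\}) / (n + 1)`, so p-values
#' are in `(0, 1]`, never exactly zero, and monotone non-increasing in
#' the score.
#'
#' @param scores Per-target score table (higher = better) or a named
#'   numeric vector.
#' @return Named numeric vector of p-values, one per target.
#' @export
empirical_pvalue <- function(scores) {
  if (is.data.frame(scores)) {
    s <- setNames(scores$score, scores$target)
  } else {
    s <- scores
  }
  n <- length(s)
  if (length(unique(s)) < 2L) {
    if (n > 0L) warning("all scores identical; every p-value is 1")
    return(setNames(rep(1, n), names(s)))
  }
  # #\{scores >= s_i\} via ranks: n - rank + 1 with max ties
  ge <- n - rank(s, ties.method = "min") + 1
  setNames((1 + ge) / (n + 1), names(s))
}

#' Fisher's method for combining independent p-values
#'
#' `X = -2 * sum(log(p))` referred to a chi-square distribution with
#' `2k` degrees of freedom.
#'
#' @param pvals Numeric vector of p-values in `(0, 1]`.
#' @return The combined p-value.
#' @export
fisher_combine <- function(pvals) {
  if (!length(pvals)) stop("empty p-value list")
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  X <- -2 * sum(log(pvals))
  pchisq(X, df = 2 * length(pvals), lower.tail = FALSE)
}

#' Default mapping of evidence channels to approaches
#'
#' Channels are grouped into three approaches: literature mining (LM),
#' neural-network inference (NNI) and domain/genomic context (DGC).
#'
#' @return Named character vector channel -> approach.
#' @export
channel_approaches <- function() {
  c("d-COCITE" = "LM", "i-COCITE" = "LM", "MLNN" = "NNI",
    "CODAcath" = "DGC", "CODApfam" = "DGC", "DORA" = "DGC",
    "GECO" = "DGC", "hiPPI" = "DGC", "GOSS" = "DGC")
}

#' Assemble a prediction matrix of per-channel p-values
#'
#' @param channel_pvals Named list: channel tag -> named p-value vector
#'   (as from [empirical_pvalue()]).
#' @param targets Optional row universe; defaults to the union of all
#'   scored targets.
#' @return Targets x channels numeric matrix with `NA` for channels that
#'   did not score a target.
#' @export
prediction_matrix <- function(channel_pvals, targets = NULL) {
  stopifnot(is.list(channel_pvals), !is.null(names(channel_pvals)))
  if (anyDuplicated(names(channel_pvals))) stop("channel tags must be unique")
  if (is.null(targets)) {
    targets <- sort(unique(unlist(lapply(channel_pvals, names))))
  }
  m <- base::matrix(NA_real_, nrow = length(targets),
                    ncol = length(channel_pvals),
                    dimnames = list(targets, names(channel_pvals)))
  for (ch in names(channel_pvals)) {
    v <- channel_pvals[[ch]]
    v <- v[names(v) %in% targets]
    m[names(v), ch] <- v
  }
  if (any(m <= 0 | m > 1, na.rm = TRUE)) stop("p-values must lie in (0, 1]")
  m
}

#' Two-stage Fisher integration into the platform score
#'
#' Stage 1 combines the available channel p-values within each approach
#' (LM, NNI, DGC) by Fisher's method; stage 2 combines the approach-level
#' p-values the same way. Missing channels or approaches are skipped with
#' the degrees of freedom reduced accordingly; targets with no channel at
#' all are excluded.
#'
#' @param matrix Targets x channels p-value matrix (see
#'   [prediction_matrix()]).
#' @param approaches Channel -> approach map; defaults to
#'   [channel_approaches()] for known tags, one approach per unknown tag.
#' @param mode `"two-stage"` (default) or `"flat"` (single Fisher across
#'   all channels, for sensitivity analysis).
#' @return A ranked data frame of class `"spip_ranking"` with columns
#'   `rank`, `target`, `p_spip` and one `p_<approach>` column per
#'   approach, sorted by ascending p (ties broken by target identifier).
#' @export
spip_integrate <- function(matrix, approaches = NULL,
                           mode = c("two-stage", "flat")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(matrix), !is.null(colnames(matrix)))
  if (is.null(approaches)) {
    approaches <- channel_approaches()[colnames(matrix)]
    names(approaches) <- colnames(matrix)
    approaches[is.na(approaches)] <- names(approaches)[is.na(approaches)]
  }
  ap_levels <- unique(unname(approaches[colnames(matrix)]))
  n_ch <- rowSums(!is.na(matrix))
  keep <- n_ch > 0L
  if (any(!keep)) {
    message(sum(!keep), " target(s) with no scored channel excluded")
  }
  m <- matrix[keep, , drop = FALSE]
  res_ap <- base::matrix(NA_real_, nrow = nrow(m), ncol = length(ap_levels),
                         dimnames = list(rownames(m), ap_levels))
  p_spip <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    if (mode == "flat") {
      p_spip[i] <- fisher_combine(row[!is.na(row)])
      next
    }
    ap_p <- c()
    for (ap in ap_levels) {
      v <- row[!is.na(row) & approaches[colnames(m)] == ap]
      if (length(v)) {
        res_ap[i, ap] <- fisher_combine(v)
        ap_p <- c(ap_p, res_ap[i, ap])
      }
    }
    p_spip[i] <- fisher_combine(ap_p)
  }
  out <- data.frame(target = rownames(m), p_spip = p_spip,
                    stringsAsFactors = FALSE)
  if (mode == "two-stage") {
    for (ap in ap_levels) out[[paste0("p_", ap)]] <- res_ap[, ap]
  }
  out <- out[order(out$p_spip, out$target), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out <- out[, c("rank", setdiff(names(out), "rank"))]
  class(out) <- c("spip_ranking", "data.frame")
  attr(out, "mode") <- mode
  out
}

#' Calibration diagnostics for a p-value sample
#'
#' Reports a Kolmogorov-Smirnov test against the uniform distribution
#' and a right-tailed Z-test on the mean of probit-transformed p-values
#' (which are standard normal under a uniform null).
#'
#' @param pvals At least 30 p-values in `(0, 1]`.
#' @param alpha Significance level for the pass/fail flags (default
#'   0.05).
#' @return List with `ks_stat`, `ks_p`, `z`, `z_p` and logical
#'   `pass` (TRUE when neither test rejects).
#' @export
calibration_check <- function(pvals, alpha = 0.05) {
  if (length(pvals) < 30L) stop("at least 30 p-values required")
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  z <- sum(qnorm(pmin(pvals, 1 - 1e-12))) / sqrt(length(pvals))
  z_p <- pnorm(z, lower.tail = FALSE)
  list(ks_stat = unname(ks$statistic), ks_p = ks$p.value,
       z = z, z_p = z_p,
       pass = ks$p.value >= alpha && z_p >= alpha)
}

#' Equal-frequency binning of a numeric series
#'
#' @param x Numeric vector.
#' @param bins Number of bins (default 10).
#' @return Integer factor of bin memberships.
#' @export
bin_equal_freq <- function(x, bins = 10L) {
  qs <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                        na.rm = TRUE))
  cut(x, breaks = qs, include.lowest = TRUE, labels = FALSE)
}

#' Normalised mutual-information distance between two discrete series
#'
#' Plug-in estimate of `D(X, Y) = 1 - I(X; Y) / H(X, Y)` in nats. `D` is
#' a metric on discrete variables: 0 when each series determines the
#' other, 1 under exact independence of the empirical joint.
#'
#' @param x,y Discrete series of equal length (factors, integers or
#'   characters). Continuous p-values should be discretised first, e.g.
#'   with [bin_equal_freq()].
#' @return `D` in `[0, 1]`.
#' @export
mi_distance <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(unique(x)) < 2L && length(unique(y)) < 2L) {
    stop("both series constant: joint entropy degenerate")
  }
  joint <- table(x, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  H <- -sum(joint[nz] * log(joint[nz]))
  expected <- outer(px, py)
  I <- sum(joint[nz] * log(joint[nz] / expected[nz]))
  1 - I / H
}

#' Pairwise MI distances between the channels of a prediction matrix
#'
#' Diagnostic mirror of the platform's channel-independence analysis:
#' p-values of every channel pair are discretised on their common
#' targets and the normalised MI distance computed.
#'
#' @param matrix Targets x channels p-value matrix.
#' @param bins Equal-frequency bins (default 10).
#' @param min_common Minimum shared targets required to report a value.
#' @return Symmetric channels x channels matrix of `D` values (`NA`
#'   where coverage is insufficient).
#' @export
channel_mi_distances <- function(matrix, bins = 10L, min_common = 30L) {
  ch <- colnames(matrix)
  D <- base::matrix(NA_real_, length(ch), length(ch),
                    dimnames = list(ch, ch))
  diag(D) <- 0
  for (i in seq_along(ch)) {
    for (j in seq_len(i - 1L)) {
      ok <- !is.na(matrix[, i]) & !is.na(matrix[, j])
      if (sum(ok) >= min_common) {
        D[i, j] <- D[j, i] <- mi_distance(
          bin_equal_freq(matrix[ok, i], bins),
          bin_equal_freq(matrix[ok, j], bins))
      }
    }
  }
  D
}
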