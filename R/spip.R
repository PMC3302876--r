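## The umbrella entry point: run every evidence channel against a
## benchmark bundle (or equivalent inputs), convert channel scores to
## empirical p-values, integrate them with two-stage Fisher, and return
## a classed result with print/summary/plot methods.

#' Integrated platform scoring of a proteome
#'
#' Runs all evidence channels -- direct/indirect co-citation, two
#' domain-fusion sources, domain over-representation, inherited
#' interactions, co-expression, semantic similarity and the feature-based
#' ensemble -- seeded by the bundle's reference set, converts each
#' channel's scores to add-one empirical p-values and combines them with
#' two-stage Fisher integration into a single ranked list.
#'
#' @param bundle A `"spip_bundle"` (from [generate_bundle()] or
#'   [read_bundle()]).
#' @param seed Integer seed for the stochastic training steps.
#' @param mode Integration mode, `"two-stage"` (default) or `"flat"`.
#' @param channels Channel tags to run (default all nine).
#' @param homology_threshold Similarity threshold for the training-set
#'   homology reduction (default 0.4); `NULL` skips reduction.
#' @param keep_models Keep the trained ensemble in the result.
#' @return Object of class `"spip"` with elements `ranking`
#'   (a `"spip_ranking"`), `pmatrix` (targets x channels p-values),
#'   `channels` (per-channel score tables), `reference`, `holdout`
#'   (when the bundle carries one) and run metadata.
#' @export
spip <- function(bundle, seed = 1L, mode = c("two-stage", "flat"),
                 channels = names(channel_approaches()),
                 homology_threshold = 0.4, keep_models = FALSE) {
  stopifnot(inherits(bundle, "spip_bundle"))
  mode <- match.arg(mode)
  ref <- bundle$seed_set
  targets <- setdiff(bundle$registry, ref$members)
  ch <- list()

  if (any(c("d-COCITE", "i-COCITE") %in% channels)) {
    net <- filter_physical(cocite_network(bundle$cocite_edges))
    cc <- score_all_cocite(net, ref)
    cc$d <- cc$d[cc$d$target %in% targets, , drop = FALSE]
    cc$i <- cc$i[cc$i$target %in% targets, , drop = FALSE]
    if ("d-COCITE" %in% channels) ch[["d-COCITE"]] <- cc$d
    if ("i-COCITE" %in% channels) ch[["i-COCITE"]] <- cc$i
  }
  if ("CODAcath" %in% channels) {
    ch[["CODAcath"]] <- coda_score_all(bundle$arch_cath, "query", ref,
                                       targets, method = "CODAcath")
  }
  if ("CODApfam" %in% channels) {
    ch[["CODApfam"]] <- coda_score_all(bundle$arch_pfam, "query", ref,
                                       targets, method = "CODApfam")
  }
  if ("DORA" %in% channels) {
    ch[["DORA"]] <- dora_protein_scores(bundle$arch_pfam, "query", ref,
                                        targets)
  }
  if ("hiPPI" %in% channels) {
    ch[["hiPPI"]] <- hippi_score_all(bundle$clustering, bundle$known, ref,
                                     targets)
  }
  if ("GECO" %in% channels) {
    ch[["GECO"]] <- score_all_geco(bundle$expression, ref,
                                   targets = targets)
  }
  if ("GOSS" %in% channels) {
    dag <- annotation_dag(bundle$dag_edges, bundle$annotations)
    ch[["GOSS"]] <- goss_score_all(dag, ref, targets)
  }
  model <- NULL
  if ("MLNN" %in% channels) {
    ft <- feature_table(bundle$features, bundle$labels)
    if (!is.null(homology_threshold) && !is.null(bundle$sim)) {
      ft <- homology_reduce(ft, bundle$sim, homology_threshold)
    }
    subsets <- greedy_feature_search(ft, seed = seed)
    model <- train_ensemble(ft, subsets, seed = seed)
    sc <- predict(model, bundle$features[targets, , drop = FALSE])
    ch[["MLNN"]] <- target_scores(names(sc), sc, "MLNN")
  }

  pvals <- lapply(ch, empirical_pvalue)
  pmatrix <- prediction_matrix(pvals, targets = sort(targets))
  ranking <- spip_integrate(pmatrix, mode = mode)
  structure(list(ranking = ranking, pmatrix = pmatrix, channels = ch,
                 reference = ref, holdout = bundle$holdout,
                 model = if (keep_models) model else NULL,
                 seed = seed, mode = mode,
                 preset = bundle$params$preset),
            class = "spip")
}

#' @export
print.spip <- function(x, ...) {
  cat(sprintf("Integrated prediction run (%s Fisher, seed %d)\n",
              x$mode, x$seed))
  cat(sprintf("  %d targets ranked, %d evidence channels, seeded by '%s' (%d proteins)\n",
              nrow(x$ranking), length(x$channels), x$reference$name,
              length(x$reference$members)))
  cat("  best-ranked targets:",
      paste(head(x$ranking$target, 5L), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.spip <- function(object, ...) {
  cov <- vapply(object$channels, nrow, integer(1))
  cat("Channel coverage (targets scored):\n")
  print(cov)
  cat("\nTop of the integrated ranking:\n")
  print(head(as.data.frame(object$ranking), 10L), digits = 4)
  if (!is.null(object$holdout)) {
    lr <- labeled_ranking(object$ranking, object$holdout)
    cv <- roc_pr_curves(lr)
    cat(sprintf("\nHoldout ('%s') recovery: ROC AUC %.3f, PR AUC %.3f\n",
                object$holdout$name, cv$auc_roc, cv$auc_pr))
  }
  invisible(object)
}

#' @export
as.data.frame.spip <- function(x, ...) as.data.frame(x$ranking)

#' ROC curve of an integrated run against a positive set
#'
#' @param x A `"spip"` object.
#' @param positives Positive set; defaults to the bundle's holdout.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.spip <- function(x, positives = x$holdout, ...) {
  if (is.null(positives)) stop("no positive set available to plot against")
  lr <- labeled_ranking(x$ranking, positives)
  cv <- roc_pr_curves(lr)
  graphics::plot(cv$roc$fpr, cv$roc$tpr, type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity (recall)",
                 main = sprintf("ROC, AUC = %.3f", cv$auc_roc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(cv)
}

#' Pair-level predictions from the ab-initio channels
#'
#' Recomputes bait-target pair scores for the purely predictive channels
#' (GECO, hiPPI, CODAcath, CODApfam), converts each channel's pair
#' scores to add-one empirical p-values, and returns the combined pair
#' table used to assemble the predicted-interaction graph.
#'
#' @param bundle A `"spip_bundle"`.
#' @param reference Bait set; defaults to the bundle's seeding set.
#' @return Data frame `p1`, `p2`, `channel`, `p`.
#' @export
pair_predictions <- function(bundle, reference = bundle$seed_set) {
  ref <- ref_members(reference)
  targets <- setdiff(bundle$registry, ref)
  out <- list()
  add <- function(pairs, channel) {
    if (!nrow(pairs)) return()
    p <- empirical_pvalue(setNames(pairs$score, NULL))
    out[[channel]] <<- data.frame(p1 = pairs$bait, p2 = pairs$target,
                                  channel = channel, p = unname(p),
                                  stringsAsFactors = FALSE)
  }
  ## GECO pairs
  mat <- bundle$expression
  miss <- rowSums(is.na(mat))
  ref_ok <- intersect(ref, rownames(mat))
  ref_ok <- ref_ok[miss[ref_ok] <= 5]
  tgt_ok <- intersect(targets, rownames(mat))
  tgt_ok <- tgt_ok[miss[tgt_ok] <= 5]
  if (length(ref_ok) && length(tgt_ok)) {
    suppressWarnings(cc <- cor(t(mat[ref_ok, , drop = FALSE]),
                               t(mat[tgt_ok, , drop = FALSE]),
                               use = "pairwise.complete.obs"))
    idx <- which(!is.na(cc), arr.ind = TRUE)
    add(data.frame(bait = ref_ok[idx[, 1L]], target = tgt_ok[idx[, 2L]],
                   score = cc[idx], stringsAsFactors = FALSE), "GECO")
  }
  ## hiPPI pairs
  cl <- bundle$clustering
  hp <- hippi_pairs(cl, bundle$known, intersect(ref, cl$protein),
                    intersect(targets, cl$protein))
  add(hp, "hiPPI")
  ## CODA pairs, both annotation sources
  for (src in c("CODAcath", "CODApfam")) {
    archs <- if (src == "CODAcath") bundle$arch_cath else bundle$arch_pfam
    qa <- archs[["query"]]
    index <- coda_fusion_index(archs, "query")
    freqs <- lapply(setNames(nm = names(archs)),
                    function(g) genome_domain_freqs(archs, g))
    rows <- list()
    for (b in intersect(ref, names(qa))) {
      tt <- intersect(targets, names(qa))
      sc <- vapply(tt, function(t) coda_pair_score(
        b, t, archs, "query", coda_form(), index, freqs), numeric(1))
      keep <- !is.na(sc)
      if (any(keep)) {
        rows[[b]] <- data.frame(bait = b, target = tt[keep],
                                score = sc[keep], stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) add(do.call(rbind, rows), src)
  }
  if (!length(out)) {
    return(data.frame(p1 = character(), p2 = character(),
                      channel = character(), p = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Hidden-hub analysis of an integrated run
#'
#' Builds the predicted-interaction graph from the ab-initio channels'
#' pair p-values, the experimental graph from the bundle's known
#' interactions, takes the top fraction of the integrated ranking as
#' candidates, and applies the hidden-hub filter.
#'
#' @param object A `"spip"` object.
#' @param bundle The bundle the run was produced from.
#' @param fraction Top fraction of the ranking to screen (default 0.02).
#' @param p_gate Pair p-value gate for the predicted graph (default
#'   0.014).
#' @param ... Thresholds passed to [hidden_hub_rank()].
#' @return List with `hubs` (ranked records), `records` (all candidate
#'   degree records), `kg`, `pg`.
#' @export
spip_hubs <- function(object, bundle, fraction = 0.02, p_gate = 0.014,
                      ...) {
  stopifnot(inherits(object, "spip"))
  known_set <- combine_reference_sets(bundle$seed_set, bundle$holdout,
                                      name = "known-module")
  kg <- evidence_graph(cbind(bundle$known[, c("p1", "p2")],
                             source = "known"), kind = "KG")
  pg <- build_pg(pair_predictions(bundle, object$reference), p_gate)
  cand <- select_top_fraction(object$ranking, fraction)
  records <- degree_stats(cand, kg, pg, known_set$members)
  list(hubs = hidden_hub_rank(records, ...), records = records,
       kg = kg, pg = pg)
}

#' Run the whole platform from a configuration
#'
#' Reads a bundle directory, runs the integrated scoring, the holdout
#' evaluation and the hidden-hub analysis, and writes every artefact
#' (per-channel scores, p-value matrix, ranking, reports, log and the
#' resolved configuration) into the output directory. A rerun with the
#' same configuration and seed reproduces the ranking byte for byte.
#'
#' @param config Path to a YAML file or a named list with keys
#'   `input_dir`, `out_dir` and optionally `seed`, `mode`, `fraction`,
#'   `p_gate`. Unknown keys are rejected.
#' @return Invisibly, the `"spip"` object.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  allowed <- c("input_dir", "out_dir", "seed", "mode", "fraction",
               "p_gate")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$input_dir) || is.null(config$out_dir)) {
    stop("config must provide input_dir and out_dir")
  }
  cfg <- utils::modifyList(list(seed = 1L, mode = "two-stage",
                                fraction = 0.02, p_gate = 0.014), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", file = logf,
                               append = TRUE, sep = "")
  cat("", file = logf)
  bundle <- read_bundle(cfg$input_dir)
  logline("loaded bundle from %s (%d proteins)", cfg$input_dir,
          length(bundle$registry))
  fit <- spip(bundle, seed = cfg$seed, mode = cfg$mode)
  for (chn in names(fit$channels)) {
    write.table(fit$channels[[chn]],
                file.path(cfg$out_dir, paste0("scores_", chn, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(data.frame(target = rownames(fit$pmatrix), fit$pmatrix,
                         check.names = FALSE),
              file.path(cfg$out_dir, "prediction_matrix.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_ranking_tsv(fit$ranking, file.path(cfg$out_dir, "ranking.tsv"))
  lr <- labeled_ranking(fit$ranking, bundle$holdout)
  cv <- roc_pr_curves(lr)
  ev <- data.frame(metric = c("auc_roc", "auc_pr", "fold_top25"),
                   value = c(cv$auc_roc, cv$auc_pr,
                             as.numeric(window_fold_enrichment(lr, 25L))))
  write.table(ev, file.path(cfg$out_dir, "evaluation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  hubs <- spip_hubs(fit, bundle, fraction = cfg$fraction,
                    p_gate = cfg$p_gate)
  write.table(hubs$hubs, file.path(cfg$out_dir, "hidden_hubs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg_out <- cfg
  cfg_out$config_hash <- substr(paste(
    tools::md5sum(file.path(cfg$out_dir, "ranking.tsv"))), 1L, 12L)
  yaml::write_yaml(cfg_out, file.path(cfg$out_dir, "config.yaml"))
  logline("ranking of %d targets written; holdout AUC %.3f",
          nrow(fit$ranking), cv$auc_roc)
  invisible(fit)
}
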