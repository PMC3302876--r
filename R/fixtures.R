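## Seeded synthetic-benchmark generator. Produces every input the
## platform consumes -- co-citation network, two domain-architecture
## sources with planted fusions, family clustering with known
## interactions, expression compendium, annotation ontology, feature
## table -- with a planted positive module so end-to-end behaviour is
## testable without any external download. The holdout part of the module
## carries signal but is excluded from the seeding set, so ranking it
## high is genuine recovery.

#' Default generation parameters
#'
#' @param preset `"default"` (planted signal), `"null"` (no signal:
#'   module indistinguishable from background) or `"strong"`.
#' @return Named list of parameters.
#' @export
bundle_params <- function(preset = c("default", "null", "strong")) {
  preset <- match.arg(preset)
  p <- list(
    n = 500L,             # proteome size
    m = 40L,              # planted module size
    seed_fraction = 0.6,  # module fraction used as the SEED-like set
    p_in = 0.25,          # co-citation edge prob within the module
    p_out = 0.02,         # background co-citation edge prob
    physical_fraction = 0.85,
    n_conditions = 30L,   # expression compendium width
    rho = 0.6,            # expression correlation of the module block
    missing_rate = 0.03,  # expression missingness per cell
    n_target_genomes = 4L,
    n_target_proteins = 250L, # proteins per target genome
    n_bg_families = 120L, # background domain superfamilies per source
    n_mod_families = 10L, # module-enriched superfamilies per source
    fusions_per_genome = 12L,
    family_size = 4L,     # sequence-family size for the clustering
    split_q_module = 0.15,   # S-level split rate inside module families
    split_q_background = 0.35,
    n_bg_known = 15L,     # background-background known interactions
    n_seed_bg_known = 20L, # seed-background known interactions
    n_features = 12L,
    n_informative = 4L,
    feature_shift = 1.2,  # SD shift of informative features in module
    n_negatives = 72L,    # negative training labels drawn from background
    preset = preset
  )
  if (preset == "null") {
    p$p_in <- p$p_out
    p$rho <- 0
    p$feature_shift <- 0
    p$planted <- FALSE
  } else if (preset == "strong") {
    p$p_in <- 0.4
    p$rho <- 0.8
    p$feature_shift <- 2
    p$planted <- TRUE
  } else {
    p$planted <- TRUE
  }
  p
}

## internal: random undirected edges among ids at prob p
rand_edges <- function(ids, p) {
  n <- length(ids)
  if (n < 2L || p <= 0) {
    return(data.frame(p1 = character(), p2 = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- which(upper.tri(base::matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(idx)) < p
  data.frame(p1 = ids[idx[keep, 1L]], p2 = ids[idx[keep, 2L]],
             stringsAsFactors = FALSE)
}

## internal: nested random S-level clusters for one family's members.
## Starts from one level-1 cluster; at each deeper level every cluster
## splits in two with probability q, so same-cluster-at-L implies
## same-cluster-below by construction.
family_slevels <- function(members, q, n_levels = 11L) {
  ids <- base::matrix("c1", nrow = length(members), ncol = n_levels)
  for (L in 2:n_levels) {
    ids[, L] <- ids[, L - 1L]
    for (cl in unique(ids[, L])) {
      incl <- which(ids[, L] == cl)
      if (length(incl) > 1L && runif(1) < q) {
        half <- sample(incl, ceiling(length(incl) / 2))
        ids[half, L] <- paste0(cl, ".", L, "a")
        ids[setdiff(incl, half), L] <- paste0(cl, ".", L, "b")
      }
    }
  }
  ids
}

## internal: architectures for one annotation source
gen_arch_source <- function(prm, registry, module, tag) {
  bg_f <- sprintf("%s_B%03d", tag, seq_len(prm$n_bg_families))
  mod_f <- sprintf("%s_M%02d", tag, seq_len(prm$n_mod_families))
  arch <- lapply(setNames(nm = registry), function(p) {
    k <- sample(1:3, 1L)
    sample(bg_f, k)
  })
  if (prm$planted) {
    for (p in module) {
      extra <- sample(mod_f, sample(1:2, 1L))
      arch[[p]] <- c(arch[[p]], extra)
    }
  }
  rows <- data.frame(genome = "query", protein = names(arch),
                     superfamilies = vapply(arch, paste, "", collapse = ","),
                     stringsAsFactors = FALSE)
  for (t in seq_len(prm$n_target_genomes)) {
    gname <- paste0("t", t)
    n_t <- prm$n_target_proteins
    prot <- sprintf("%s_%s_p%03d", tag, gname, seq_len(n_t))
    archs_t <- vapply(prot, function(p)
      paste(sample(bg_f, sample(1:3, 1L)), collapse = ","), "")
    # planted fusion proteins carrying pairs of module-enriched families
    fus_pool <- if (prm$planted) mod_f else bg_f
    for (f in seq_len(prm$fusions_per_genome)) {
      pair <- sample(fus_pool, 2L)
      archs_t <- c(archs_t, paste(pair, collapse = ","))
      prot <- c(prot, sprintf("%s_%s_fus%02d", tag, gname, f))
    }
    rows <- rbind(rows, data.frame(genome = gname, protein = prot,
                                   superfamilies = unname(archs_t),
                                   stringsAsFactors = FALSE))
  }
  domain_archs(rows)
}

#' Generate a synthetic benchmark bundle
#'
#' All evidence channels carry signal for the planted module under the
#' `"default"` and `"strong"` presets: module members co-cite
#' preferentially, carry module-enriched superfamilies with planted
#' fusions in the target genomes, inherit module interactions at high
#' S-levels, co-express, share deep (low-frequency) ontology terms, and
#' have shifted informative features. Under `"null"` the module is
#' statistically indistinguishable from background.
#'
#' @param params Parameter list from [bundle_params()]; individual
#'   entries may be overridden via `...`.
#' @param seed Integer RNG seed; the bundle is reproducible byte-for-byte
#'   given the seed.
#' @param ... Overrides for single parameters, e.g. `n = 200`.
#' @return Object of class `"spip_bundle"`.
#' @export
generate_bundle <- function(params = bundle_params(), seed = 1L, ...) {
  prm <- utils::modifyList(params, list(...))
  if (prm$m > prm$n) stop("module larger than proteome (m > n)")
  if (prm$n < 50L || prm$m < 10L) stop("need n >= 50 and m >= 10")
  if (prm$p_in < prm$p_out) stop("infeasible: p_in < p_out")
  if (prm$rho < 0 || prm$rho >= 1) stop("rho must be in [0, 1)")
  set.seed(seed)
  registry <- sprintf("P%04d", seq_len(prm$n))
  module <- sort(sample(registry, prm$m))
  n_seed <- round(prm$seed_fraction * prm$m)
  seed_members <- sort(sample(module, n_seed))
  holdout <- setdiff(module, seed_members)
  seed_set <- reference_set("SEED", seed_members, registry)
  holdout_set <- reference_set("EXPERT", holdout, registry)

  ## -- co-citation network ------------------------------------------
  bg <- rand_edges(registry, prm$p_out)
  inmod <- rand_edges(module, max(prm$p_in - prm$p_out, 0))
  edges <- unique(rbind(bg, inmod))
  cls <- ifelse(runif(nrow(edges)) < prm$physical_fraction, "physical",
                sample(c("genetic", "regulatory"), nrow(edges),
                       replace = TRUE))
  cocite_edges <- cbind(edges, relation_class = cls,
                        stringsAsFactors = FALSE)

  ## -- domain architectures (two annotation sources) ----------------
  arch_cath <- gen_arch_source(prm, registry, module, "cath")
  arch_pfam <- gen_arch_source(prm, registry, module, "pfam")

  ## -- family clustering and known interactions ---------------------
  fam_size <- prm$family_size
  n_mod_fam <- ceiling(prm$m / fam_size)
  mod_fams <- split(module, rep(seq_len(n_mod_fam), each = fam_size,
                                length.out = prm$m))
  backg <- setdiff(registry, module)
  n_bg_fam <- ceiling(length(backg) / fam_size)
  bg_fams <- split(sample(backg), rep(seq_len(n_bg_fam), each = fam_size,
                                      length.out = length(backg)))
  fam_list <- c(setNames(mod_fams, sprintf("FAMM%02d", seq_along(mod_fams))),
                setNames(bg_fams, sprintf("FAMB%03d", seq_along(bg_fams))))
  rows <- list()
  for (f in names(fam_list)) {
    mem <- fam_list[[f]]
    q <- if (startsWith(f, "FAMM") && prm$planted) prm$split_q_module
    else prm$split_q_background
    lv <- family_slevels(mem, q)
    lv[] <- paste(f, lv, sep = ":")
    rows[[f]] <- data.frame(protein = mem, family = f,
                            levels = apply(lv, 1L, paste, collapse = ","),
                            stringsAsFactors = FALSE)
  }
  clustering <- family_clustering(do.call(rbind, rows))
  ## known interactions: concentrated between module families when
  ## planted, plus background support so inheritance scores exist
  ## genome-wide
  known <- list()
  ev_pool <- c("Y2H", "coIP", "TAP", "crystal")
  sp_pool <- c("HSA", "MMU", "DME")
  add_known <- function(p1, p2) {
    n_ev <- sample(1:3, 1L)
    n_sp <- sample(1:2, 1L)
    data.frame(p1 = p1, p2 = p2,
               evidence_types = paste(sample(ev_pool, n_ev), collapse = ","),
               species = paste(sample(sp_pool, n_sp), collapse = ","),
               stringsAsFactors = FALSE)
  }
  if (prm$planted) {
    for (i in seq_along(mod_fams)) {
      j <- (i %% length(mod_fams)) + 1L
      a <- intersect(mod_fams[[i]], seed_members)
      b <- intersect(mod_fams[[j]], seed_members)
      if (length(a) && length(b)) {
        known[[length(known) + 1L]] <- add_known(sample(a, 1L),
                                                 sample(b, 1L))
      }
    }
  }
  ## seed-background interactions in every preset, so the inheritance
  ## channel has genome-wide coverage and a proper score distribution
  for (k in seq_len(prm$n_seed_bg_known)) {
    known[[length(known) + 1L]] <- add_known(sample(seed_members, 1L),
                                             sample(backg, 1L))
  }
  for (k in seq_len(prm$n_bg_known)) {
    pq <- sample(backg, 2L)
    known[[length(known) + 1L]] <- add_known(pq[1L], pq[2L])
  }
  known <- do.call(rbind, known)

  ## -- expression compendium ----------------------------------------
  nc <- prm$n_conditions
  expr <- base::matrix(rnorm(prm$n * nc), nrow = prm$n,
                       dimnames = list(registry, sprintf("cond%02d",
                                                         seq_len(nc))))
  if (prm$rho > 0) {
    f <- rnorm(nc)
    for (p in module) {
      expr[p, ] <- sqrt(prm$rho) * f + sqrt(1 - prm$rho) * rnorm(nc)
    }
  }
  n_miss <- pmin(rbinom(prm$n, nc, prm$missing_rate), 8L)
  for (i in seq_len(prm$n)) {
    if (n_miss[i] > 0L) expr[i, sample(nc, n_miss[i])] <- NA
  }

  ## -- annotation ontology ------------------------------------------
  broad <- sprintf("T1_%02d", 1:6)
  mid <- sprintf("T2_%02d", 1:24)
  deep <- sprintf("T3_%02d", 1:48)
  dag_edges <- rbind(
    data.frame(child = broad, parent = "T0000", stringsAsFactors = FALSE),
    data.frame(child = mid, parent = broad[((seq_along(mid) - 1) %% 6) + 1],
               stringsAsFactors = FALSE),
    data.frame(child = deep, parent = mid[((seq_along(deep) - 1) %% 24) + 1],
               stringsAsFactors = FALSE))
  mod_terms <- deep[1:3]
  other_terms <- c(mid, setdiff(deep, mod_terms))
  ann <- list()
  for (p in registry) {
    ts <- sample(other_terms, sample(2:4, 1L))
    if (prm$planted && p %in% module) {
      ts <- c(sample(mod_terms, sample(1:2, 1L)), sample(ts, 2L))
    }
    ann[[p]] <- unique(ts)
  }
  annotations <- data.frame(
    protein = rep(names(ann), lengths(ann)),
    term = unlist(ann, use.names = FALSE), stringsAsFactors = FALSE)

  ## -- feature table, labels, similarity ----------------------------
  d <- prm$n_features
  feats <- base::matrix(rnorm(prm$n * d), nrow = prm$n,
                        dimnames = list(registry,
                                        sprintf("F%02d", seq_len(d))))
  if (prm$feature_shift > 0) {
    feats[module, seq_len(prm$n_informative)] <-
      feats[module, seq_len(prm$n_informative)] + prm$feature_shift
  }
  negs <- sort(sample(backg, prm$n_negatives))
  labels <- setNames(c(rep("positive", length(seed_members)),
                       rep("negative", length(negs))),
                     c(seed_members, negs))
  sim <- base::matrix(runif(prm$n * prm$n, 0, 0.3), prm$n, prm$n,
                      dimnames = list(registry, registry))
  sim[lower.tri(sim)] <- t(sim)[lower.tri(sim)]
  for (f in fam_list) {       # family members are sequence-similar
    sim[f, f] <- runif(length(f)^2, 0.45, 0.9)
    sim[f, f][lower.tri(sim[f, f])] <- t(sim[f, f])[lower.tri(sim[f, f])]
  }
  diag(sim) <- 1

  structure(list(
    registry = registry, module = module, seed_set = seed_set,
    holdout = holdout_set, cocite_edges = cocite_edges,
    arch_cath = arch_cath, arch_pfam = arch_pfam,
    clustering = clustering, known = known, expression = expr,
    dag_edges = dag_edges, annotations = annotations,
    features = feats, labels = labels, sim = sim,
    params = prm, seed = seed), class = "spip_bundle")
}

#' Generate a small network fixture with a planted hidden hub
#'
#' Builds channel-level pair p-values and an experimental edge list in
#' which one protein has very few experimentally known interactions but
#' many predicted ones, almost all into the known module -- the
#' signature the hidden-hub filter is designed to find. The other
#' candidates are either well-characterised (high known degree) or
#' unspecific (predictions spread outside the module).
#'
#' @param seed Integer RNG seed.
#' @param n Proteome size (default 120).
#' @param n_module Known-module size (default 30).
#' @return List with `channel_pairs` (`p1`, `p2`, `channel`, `p`),
#'   `kg_edges` (`p1`, `p2`, `source`), `module`, `candidates`, `hub`.
#' @export
generate_hub_fixture <- function(seed = 1L, n = 120L, n_module = 30L) {
  set.seed(seed)
  registry <- sprintf("H%03d", seq_len(n))
  module <- registry[seq_len(n_module)]
  hub <- "HUB01"
  decoys <- sprintf("DEC%02d", 1:8)
  cand <- c(hub, decoys)
  chs <- c("GECO", "hiPPI", "CODAcath", "CODApfam")
  rows <- list()
  pred <- function(p1, p2, p) {
    data.frame(p1 = p1, p2 = p2, channel = sample(chs, length(p1),
                                                  replace = TRUE),
               p = p, stringsAsFactors = FALSE)
  }
  # hub: many confident predictions, ~90% into the module
  k_mod <- max(5L, round(0.85 * n_module))
  tgt <- c(sample(module, k_mod), sample(setdiff(registry, module), 4L))
  rows$hub <- pred(hub, tgt, runif(k_mod + 4L, 1e-4, 0.013))
  # decoys: half are well known (dense KG), half unspecific in PG
  kg <- list(data.frame(p1 = hub, p2 = sample(module, 2L),
                        source = "known", stringsAsFactors = FALSE))
  for (i in seq_along(decoys)) {
    d <- decoys[i]
    if (i <= 4L) {
      kg[[d]] <- data.frame(p1 = d, p2 = sample(registry, 12L),
                            source = "known", stringsAsFactors = FALSE)
      rows[[d]] <- pred(d, sample(module, 15L), runif(15L, 1e-4, 0.013))
    } else {
      out_t <- sample(setdiff(registry, module), 25L)
      rows[[d]] <- pred(d, c(out_t, sample(module, 5L)),
                        runif(30L, 1e-4, 0.013))
    }
  }
  # background predictions that fail the gate
  bgp <- pred(sample(registry, 150L, replace = TRUE),
              sample(registry, 150L, replace = TRUE),
              runif(150L, 0.05, 1))
  list(channel_pairs = do.call(rbind, c(rows, list(bgp),
                                        make.row.names = FALSE)),
       kg_edges = do.call(rbind, c(kg, make.row.names = FALSE)),
       module = module, candidates = cand, hub = hub)
}

#' @export
print.spip_bundle <- function(x, ...) {
  cat(sprintf(
    "Synthetic benchmark bundle (preset '%s', seed %d):\n", x$params$preset,
    x$seed))
  cat(sprintf("  %d proteins, module of %d (%d seeding / %d holdout)\n",
              length(x$registry), length(x$module),
              length(x$seed_set$members), length(x$holdout$members)))
  cat(sprintf("  %d co-citation edges, %d known interactions, %d conditions, %d features\n",
              nrow(x$cocite_edges), nrow(x$known),
              ncol(x$expression), ncol(x$features)))
  invisible(x)
}

#' Write a bundle to a directory of plain-text files
#'
#' Emits every input in the dialect its reader expects, plus a manifest
#' of MD5 checksums for integrity checks.
#'
#' @param bundle A `"spip_bundle"`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame (`file`, `md5`).
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "spip_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, file) {
    write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wtsv(bundle$cocite_edges, "cocite.tsv")
  arch_df <- function(a) {
    do.call(rbind, lapply(names(a), function(g) {
      data.frame(genome = g, protein = names(a[[g]]),
                 superfamilies = vapply(a[[g]], paste, "", collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  }
  wtsv(arch_df(bundle$arch_cath), "arch_cath.tsv")
  wtsv(arch_df(bundle$arch_pfam), "arch_pfam.tsv")
  cl <- bundle$clustering
  wtsv(data.frame(protein = cl$protein, family = cl$family,
                  levels = apply(cl$levels, 1L, paste, collapse = ","),
                  stringsAsFactors = FALSE), "clustering.tsv")
  wtsv(bundle$known, "known.tsv")
  wtsv(data.frame(gene = rownames(bundle$expression), bundle$expression,
                  check.names = FALSE, stringsAsFactors = FALSE),
       "expression.tsv")
  wtsv(bundle$dag_edges, "dag.tsv")
  wtsv(bundle$annotations, "annotations.tsv")
  wtsv(data.frame(protein = rownames(bundle$features), bundle$features,
                  check.names = FALSE, stringsAsFactors = FALSE),
       "features.tsv")
  wtsv(data.frame(protein = names(bundle$labels),
                  label = unname(bundle$labels), stringsAsFactors = FALSE),
       "labels.tsv")
  writeLines(bundle$seed_set$members, file.path(dir, "seed.txt"))
  writeLines(bundle$holdout$members, file.path(dir, "expert.txt"))
  writeLines(bundle$registry, file.path(dir, "registry.txt"))
  wtsv(data.frame(protein = rownames(bundle$sim),
                  round(bundle$sim, 6), check.names = FALSE,
                  stringsAsFactors = FALSE), "similarity.tsv")
  yaml::write_yaml(bundle$params, file.path(dir, "params.yaml"))
  writeLines(as.character(bundle$seed), file.path(dir, "rng_seed.txt"))
  files <- sort(setdiff(list.files(dir), "manifest.tsv"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(dir, files))),
                         stringsAsFactors = FALSE)
  wtsv(manifest, "manifest.tsv")
  invisible(manifest)
}

#' Read a bundle back from a directory
#'
#' Verifies the manifest checksums before loading.
#'
#' @param dir Directory written by [write_bundle()].
#' @param check_manifest Verify MD5 checksums (default `TRUE`).
#' @return A `"spip_bundle"`.
#' @export
read_bundle <- function(dir, check_manifest = TRUE) {
  rtsv <- function(file) read_tsv_strict(file.path(dir, file))
  if (check_manifest) {
    manifest <- rtsv("manifest.tsv")
    cur <- unname(tools::md5sum(file.path(dir, manifest$file)))
    bad <- manifest$file[cur != manifest$md5]
    if (length(bad)) stop("checksum mismatch: ", paste(bad, collapse = ", "))
  }
  prm <- yaml::read_yaml(file.path(dir, "params.yaml"))
  expr_df <- rtsv("expression.tsv")
  expr <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expr) <- expr_df$gene
  feat_df <- rtsv("features.tsv")
  feats <- as.matrix(feat_df[, -1, drop = FALSE])
  rownames(feats) <- feat_df$protein
  lab_df <- rtsv("labels.tsv")
  registry <- readLines(file.path(dir, "registry.txt"))
  seed_members <- readLines(file.path(dir, "seed.txt"))
  holdout <- readLines(file.path(dir, "expert.txt"))
  sim_df <- rtsv("similarity.tsv")
  sim <- as.matrix(sim_df[, -1, drop = FALSE])
  rownames(sim) <- sim_df$protein
  structure(list(
    registry = registry,
    module = sort(c(seed_members, holdout)),
    seed_set = reference_set("SEED", seed_members, registry),
    holdout = reference_set("EXPERT", holdout, registry),
    cocite_edges = rtsv("cocite.tsv"),
    arch_cath = domain_archs(rtsv("arch_cath.tsv")),
    arch_pfam = domain_archs(rtsv("arch_pfam.tsv")),
    clustering = family_clustering(rtsv("clustering.tsv")),
    known = rtsv("known.tsv"),
    expression = expr,
    dag_edges = rtsv("dag.tsv"),
    annotations = rtsv("annotations.tsv"),
    features = feats,
    labels = setNames(lab_df$label, lab_df$protein),
    sim = sim, params = prm,
    seed = as.integer(readLines(file.path(dir, "rng_seed.txt")))),
    class = "spip_bundle")
}
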