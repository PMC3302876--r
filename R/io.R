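## Strict readers and writers for the plain-text formats the platform
## consumes: tagged edge lists, domain-architecture tables, S-level
## clusterings, known-interaction tables, expression matrices, ontology
## edges (TSV dialect or a minimal OBO subset), annotation tables,
## feature tables and ranked lists. All files are TSV with a mandatory
## header row, `NA` as the missing sentinel, UTF-8, and CRLF tolerated.

## internal: read a TSV with a header, reporting malformed lines
read_tsv_strict <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (!length(lines)) stop("empty file: ", path)
  ncol_hdr <- length(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]])
  nc <- vapply(strsplit(lines, "\t", fixed = TRUE), length, integer(1))
  bad <- which(nc != ncol_hdr & nzchar(lines))
  if (length(bad)) {
    stop("malformed line ", bad[1L], " in ", path, ": expected ",
         ncol_hdr, " fields, found ", nc[bad[1L]])
  }
  df <- read.delim(text = lines, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = "NA")
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      stop("missing column(s) in ", path, ": ",
           paste(missing, collapse = ", "))
    }
  }
  df
}

#' Read a tagged edge list
#'
#' Format: `p1<TAB>p2[<TAB>relation_class]` with a header row.
#'
#' @param path File path.
#' @return Data frame with the edge columns.
#' @export
read_edge_tsv <- function(path) read_tsv_strict(path, c("p1", "p2"))

#' Read a domain-architecture table
#'
#' Format: `genome<TAB>protein<TAB>sf1,sf2,...`; duplicated proteins
#' within a genome are an error.
#'
#' @param path File path.
#' @return A `"domain_archs"` object.
#' @export
read_arch_tsv <- function(path) {
  domain_archs(read_tsv_strict(path, c("genome", "protein", "superfamilies")))
}

#' Read an S-level family clustering
#'
#' Format: `protein<TAB>family<TAB>l1,l2,...,l11`.
#'
#' @param path File path.
#' @return A `"family_clustering"`.
#' @export
read_clustering_tsv <- function(path) {
  family_clustering(read_tsv_strict(path, c("protein", "family", "levels")))
}

#' Read a known-interaction table
#'
#' Format: `p1<TAB>p2<TAB>evidence_types(csv)<TAB>species(csv)`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_known_tsv <- function(path) {
  read_tsv_strict(path, c("p1", "p2", "evidence_types", "species"))
}

#' Read an expression matrix
#'
#' Genes as rows (first column `gene`), condition identifiers in the
#' header, `NA` for missing values; duplicated genes are an error.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv_strict(path, "gene")
  if (anyDuplicated(df$gene)) {
    stop("duplicated gene row: ", df$gene[duplicated(df$gene)][1L])
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$gene
  m
}

#' Read ontology edges from a TSV dialect
#'
#' Format: `child<TAB>parent`.
#'
#' @param path File path.
#' @return Data frame with `child`, `parent`.
#' @export
read_dag_tsv <- function(path) read_tsv_strict(path, c("child", "parent"))

#' Read ontology edges from a minimal OBO subset
#'
#' Parses `[Term]` stanzas with `id:` and `is_a:` lines (comments after
#' `!` stripped); everything else is ignored.
#'
#' @param path File path.
#' @return Data frame with `child`, `parent`.
#' @export
read_obo <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  child <- parent <- character()
  cur <- NA_character_
  in_term <- FALSE
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      in_term <- identical(ln, "[Term]")
      cur <- NA_character_
    } else if (in_term && startsWith(ln, "id:")) {
      cur <- trimws(sub("^id:", "", ln))
    } else if (in_term && startsWith(ln, "is_a:") && !is.na(cur)) {
      p <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      child <- c(child, cur)
      parent <- c(parent, p)
    }
  }
  data.frame(child = child, parent = parent, stringsAsFactors = FALSE)
}

#' Read an annotation table
#'
#' Format: `protein<TAB>term`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_annotations_tsv <- function(path) {
  read_tsv_strict(path, c("protein", "term"))
}

#' Read a labelled feature table
#'
#' Proteins as rows (first column `protein`), features in the header;
#' duplicated proteins are an error.
#'
#' @param path File path.
#' @return Numeric matrix with protein rownames.
#' @export
read_feature_tsv <- function(path) {
  df <- read_tsv_strict(path, "protein")
  if (anyDuplicated(df$protein)) {
    stop("duplicated protein row: ", df$protein[duplicated(df$protein)][1L])
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$protein
  m
}

#' Write and read a ranked list
#'
#' Format: `rank<TAB>target<TAB>p_spip[<TAB>per-approach p columns]`.
#'
#' @param ranking A `"spip_ranking"`.
#' @param path File path.
#' @return `write_ranking_tsv` invisibly returns the path;
#'   `read_ranking_tsv` the data frame.
#' @export
write_ranking_tsv <- function(ranking, path) {
  write.table(as.data.frame(ranking), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking_tsv
#' @export
read_ranking_tsv <- function(path) {
  out <- read_tsv_strict(path, c("rank", "target", "p_spip"))
  class(out) <- c("spip_ranking", "data.frame")
  out
}

#' Read a one-identifier-per-line reference set
#'
#' @param path File path.
#' @param name Set name (defaults to the file name).
#' @return A `"reference_set"`.
#' @export
read_reference_txt <- function(path, name = basename(path)) {
  ids <- sub("\r$", "", readLines(path, warn = FALSE))
  reference_set(name, ids[nzchar(ids)])
}
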