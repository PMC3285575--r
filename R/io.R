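#' Read a gene-by-experiment expression matrix
#'
#' Reads a tab-separated table whose first row holds experiment identifiers,
#' first column holds gene identifiers, and body holds numeric values
#' (log2 normalized expression intensities). Row and column order are
#' preserved exactly as in the file.
#'
#' @param path Path to a tab-separated text file.
#' @return A numeric matrix with gene identifiers as row names and
#'   experiment identifiers as column names.
#' @export
read_expression_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop_format("expression file '%s' has no data rows", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  # header may or may not carry a leading corner cell for the gene-id column
  body <- fields[-1L]
  width <- length(body[[1L]])
  exp_ids <- if (length(header) == width) header[-1L] else header
  if (length(exp_ids) != width - 1L) {
    stop_format("header has %d experiment ids but data rows have %d value columns",
                length(exp_ids), width - 1L)
  }
  check_gene_ids(exp_ids, "experiment")
  n <- length(body)
  gene_ids <- character(n)
  values <- matrix(NA_real_, n, width - 1L)
  for (i in seq_len(n)) {
    row <- body[[i]]
    if (length(row) != width) {
      stop_format("ragged row at line %d: expected %d fields, found %d",
                  i + 1L, width, length(row))
    }
    gene_ids[[i]] <- row[[1L]]
    v <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[[1L]]
      stop_format("non-numeric value '%s' at line %d, column %d",
                  row[-1L][[bad]], i + 1L, bad + 1L)
    }
    values[i, ] <- v
  }
  check_gene_ids(gene_ids, "gene")
  if (!all(is.finite(values))) stop_format("expression matrix contains non-finite values")
  dimnames(values) <- list(gene_ids, exp_ids)
  values
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of [read_expression_matrix()]; values are written at full
#' precision so the round trip is lossless.
#'
#' @param x Numeric matrix with gene row names and experiment column names.
#' @param path Output file path.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(x)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], format(x[i, ], digits = 17, trim = TRUE,
                                   scientific = FALSE)), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read gene-to-term annotations restricted to a gene universe
#'
#' Expects two tab-separated columns (gene id, term id) with an optional
#' third free-text description column. Genes outside `universe` are dropped;
#' terms left empty after the restriction are dropped. The number of
#' retained terms `M` is the family size used by the Benjamini-Hochberg
#' correction.
#'
#' @param path Path to the annotation file.
#' @param universe Character vector of gene identifiers defining the
#'   analysis universe.
#' @return An `annotation_set`: list with `terms` (named list term id ->
#'   character vector of gene ids), `descriptions` (named character),
#'   `n_terms` and `universe`.
#' @export
read_go_annotations <- function(path, universe) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_format("annotation file '%s' is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  genes <- character(length(fields))
  terms <- character(length(fields))
  desc <- character(length(fields))
  for (i in seq_along(fields)) {
    row <- fields[[i]]
    if (length(row) < 2L) stop_format("malformed annotation line %d (need gene<TAB>term)", i)
    genes[[i]] <- row[[1L]]
    terms[[i]] <- row[[2L]]
    desc[[i]] <- if (length(row) >= 3L) row[[3L]] else ""
  }
  keep <- genes %in% universe
  genes <- genes[keep]; term_kept <- terms[keep]; desc_kept <- desc[keep]
  term_map <- split(genes, term_kept)
  term_map <- lapply(term_map, unique)
  term_map <- term_map[lengths(term_map) > 0L]
  descriptions <- vapply(names(term_map), function(t) {
    d <- desc_kept[term_kept == t]
    d <- d[nzchar(d)]
    if (length(d)) d[[1L]] else ""
  }, character(1))
  structure(list(terms = term_map,
                 descriptions = descriptions,
                 n_terms = length(term_map),
                 universe = universe),
            class = "annotation_set")
}

#' Read an operon definition file
#'
#' One operon per line: operon id followed by its member gene ids,
#' tab-separated.
#'
#' @param path Path to the operon file.
#' @return Named list operon id -> ordered character vector of gene ids.
#' @export
read_operons <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_format("operon file '%s' is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, character(1), 1L)
  check_gene_ids(ids, "operon")
  ops <- lapply(fields, function(row) {
    if (length(row) < 2L) stop_format("operon '%s' has no member genes", row[[1L]])
    row[-1L]
  })
  names(ops) <- ids
  ops
}

#' Read a replicate map
#'
#' One base experiment per line: base id followed by its replicate column
#' ids, tab-separated.
#'
#' @param path Path to the replicate map file.
#' @return Named list base experiment id -> character vector of replicate
#'   column ids.
#' @export
read_replicate_map <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_format("replicate map '%s' is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, character(1), 1L)
  check_gene_ids(ids, "base experiment")
  reps <- lapply(fields, function(row) row[-1L])
  names(reps) <- ids
  all_cols <- unlist(reps, use.names = FALSE)
  if (anyDuplicated(all_cols)) {
    stop_format("replicate groups are not disjoint: column '%s' appears twice",
                all_cols[duplicated(all_cols)][[1L]])
  }
  reps
}

#' Write a network edge list
#'
#' One line per undirected link, each link written once with the
#' lexicographically smaller endpoint first: gene, Blattner number (empty if
#' unknown), target gene, target Blattner number, tab-separated.
#'
#' @param network A `threshold_network`.
#' @param path Output file path.
#' @param blattner Optional named character vector mapping gene id to
#'   Blattner number.
#' @export
write_edge_list <- function(network, path, blattner = NULL) {
  stopifnot(inherits(network, "threshold_network"))
  A <- network$adjacency
  idx <- which(upper.tri(A) & A == 1L, arr.ind = TRUE)
  bn <- function(g) {
    if (is.null(blattner)) return(rep("", length(g)))
    b <- blattner[g]
    ifelse(is.na(b), "", b)
  }
  g1 <- network$gene_ids[idx[, 1L]]
  g2 <- network$gene_ids[idx[, 2L]]
  swap <- g2 < g1
  tmp <- g1[swap]; g1[swap] <- g2[swap]; g2[swap] <- tmp
  ord <- order(g1, g2)
  lines <- paste(g1[ord], bn(g1[ord]), g2[ord], bn(g2[ord]), sep = "\t")
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Read an edge list written by [write_edge_list()]
#'
#' @param path Path to the edge-list file.
#' @param gene_ids Gene universe defining node set and order of the
#'   reconstructed network.
#' @param z0 Threshold recorded on the returned network (metadata only).
#' @return A `threshold_network` over `gene_ids`.
#' @export
read_edge_list <- function(path, gene_ids, z0 = NA_real_) {
  check_gene_ids(gene_ids)
  n <- length(gene_ids)
  A <- matrix(0L, n, n, dimnames = list(gene_ids, gene_ids))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  for (i in seq_along(lines)) {
    row <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    # a trailing empty Blattner field may be dropped by the split
    if (length(row) < 3L) stop_format("malformed edge line %d", i)
    a <- row[[1L]]; b <- row[[3L]]
    if (!a %in% gene_ids || !b %in% gene_ids) {
      stop_format("edge line %d references a gene outside the universe", i)
    }
    A[a, b] <- 1L; A[b, a] <- 1L
  }
  as_threshold_network(A, z0 = z0)
}

#' Write a community membership table
#'
#' One line per gene in the partition's gene order: gene id, Blattner number
#' (empty if unknown), community label.
#'
#' @param partition A `network_partition` or a named integer vector of
#'   community labels.
#' @param path Output file path.
#' @param blattner Optional named character vector of Blattner numbers.
#' @export
write_membership <- function(partition, path, blattner = NULL) {
  mem <- membership_vector(partition)
  if (length(mem) == 0L) stop_format("partition has no genes")
  bn <- if (is.null(blattner)) rep("", length(mem)) else {
    b <- blattner[names(mem)]
    ifelse(is.na(b), "", b)
  }
  writeLines(paste(names(mem), bn, mem, sep = "\t"), path)
  invisible(path)
}

#' Read a membership table written by [write_membership()]
#'
#' @param path Path to the membership file.
#' @return Named integer vector gene id -> community label.
#' @export
read_membership <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_format("membership file '%s' is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  genes <- vapply(fields, `[[`, character(1), 1L)
  labels <- vapply(fields, function(row) {
    v <- suppressWarnings(as.integer(row[[length(row)]]))
    if (is.na(v)) stop_format("non-integer community label for gene '%s'", row[[1L]])
    v
  }, integer(1))
  check_gene_ids(genes)
  stats::setNames(labels, genes)
}

# Accept either a network_partition or a bare named label vector.
membership_vector <- function(partition) {
  if (inherits(partition, "network_partition")) return(partition$membership)
  if (is.numeric(partition) && !is.null(names(partition))) {
    return(stats::setNames(as.integer(partition), names(partition)))
  }
  stop_format("expected a network_partition or a named label vector")
}
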