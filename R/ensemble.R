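#' Run an ensemble of replicate partitionings
#'
#' Applies [partition_network()] `runs` times with per-run seeds derived
#' from `seed`, exploiting the stochasticity of the optimizer to sample the
#' family of near-optimal partitions.
#'
#' @param network A `threshold_network`.
#' @param runs Number of replicate runs (>= 1).
#' @param seed Integer master seed; the ensemble is reproducible from
#'   `(seed, runs)`.
#' @return A `partition_ensemble`: list with `partitions` (list of
#'   `network_partition`), `seeds`, `gene_ids`.
#' @export
run_ensemble <- function(network, runs = 10L, seed = 1L) {
  stopifnot(inherits(network, "threshold_network"), runs >= 1L)
  seeds <- vapply(seq_len(runs), function(r) derive_seed(seed, r), integer(1))
  partitions <- lapply(seeds, function(s) partition_network(network, seed = s))
  structure(list(partitions = partitions, seeds = seeds,
                 gene_ids = network$gene_ids),
            class = "partition_ensemble")
}

#' Co-classification matrix of a partition ensemble
#'
#' `C[i, j]` is the proportion of the ensemble's partitionings in which
#' genes i and j share a community; the diagonal is 1 and every entry is a
#' multiple of `1/R`.
#'
#' @param ensemble A `partition_ensemble`, or a plain list of
#'   `network_partition`s / named label vectors over a common gene set.
#' @return A `coclassification`: list with `C` (proportion matrix),
#'   `counts` (integer agreement counts), `R` (ensemble size), `gene_ids`.
#' @export
coclassification <- function(ensemble) {
  parts <- if (inherits(ensemble, "partition_ensemble")) ensemble$partitions else ensemble
  stopifnot(length(parts) >= 1L)
  mems <- lapply(parts, membership_vector)
  gene_ids <- names(mems[[1L]])
  n <- length(gene_ids)
  counts <- matrix(0L, n, n, dimnames = list(gene_ids, gene_ids))
  for (mem in mems) {
    if (!identical(sort(names(mem)), sort(gene_ids))) {
      stop_format("ensemble partitions do not cover the same gene set")
    }
    v <- mem[gene_ids]
    counts <- counts + outer(v, v, "==")
  }
  R <- length(mems)
  structure(list(C = counts / R, counts = counts, R = R, gene_ids = gene_ids),
            class = "coclassification")
}

#' Extract core communities from a co-classification matrix
#'
#' At the default `tau = 1` a core community is an equivalence class of
#' genes that share a community in *every* partitioning (agreement counts
#' equal to R exactly, so no floating-point tolerance is involved). For
#' `tau < 1` co-classification at rate `tau` is not transitive, so cores
#' are the connected components of the graph linking pairs with
#' `C >= tau`; either way the cores partition the gene universe. Cores are
#' numbered from 1 by decreasing size (ties broken by the
#' lexicographically smallest member).
#'
#' @param C A `coclassification`.
#' @param tau Co-classification threshold in (0, 1].
#' @return A `core_communities`: list with `sets` (list of gene-id vectors,
#'   decreasing size), `labels` (named integer, 1-based core number per
#'   gene), `tau`, `sizes`.
#' @export
core_communities <- function(C, tau = 1) {
  stopifnot(inherits(C, "coclassification"), tau > 0, tau <= 1)
  keep <- if (tau == 1) C$counts == C$R else C$C >= tau
  diag(keep) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(keep, mode = "undirected")
  comp <- igraph::components(g)
  sets <- split(C$gene_ids, comp$membership)
  first <- vapply(sets, function(s) min(s), character(1))
  ord <- order(-lengths(sets), first)
  sets <- unname(sets[ord])
  labels <- integer(length(C$gene_ids))
  names(labels) <- C$gene_ids
  for (i in seq_along(sets)) labels[sets[[i]]] <- i
  structure(list(sets = sets, labels = labels, tau = tau,
                 sizes = lengths(sets)),
            class = "core_communities")
}

#' @export
print.core_communities <- function(x, ...) {
  cat(sprintf("core_communities: %d cores over %d genes (tau = %s); sizes: %s\n",
              length(x$sets), length(x$labels), format(x$tau),
              paste(utils::head(x$sizes, 10L), collapse = ", ")))
  invisible(x)
}

#' Fraction of fine-level co-core pairs preserved at a coarse level
#'
#' Among unordered gene pairs that share a core community at the fine
#' (higher-threshold) level, the proportion that also share a core at the
#' coarse (lower-threshold) level. Equals 1 exactly when the fine cores are
#' nested inside the coarse cores.
#'
#' @param fine,coarse `core_communities` over the same gene universe.
#' @return Proportion in `[0, 1]`, or `NA` (with a warning) when the fine
#'   level has no co-core pair.
#' @export
hierarchy_fraction <- function(fine, coarse) {
  stopifnot(inherits(fine, "core_communities"), inherits(coarse, "core_communities"))
  if (!setequal(names(fine$labels), names(coarse$labels))) {
    stop_format("core community sets are over different gene universes")
  }
  total <- 0
  kept <- 0
  for (s in fine$sets) {
    nf <- length(s)
    if (nf < 2L) next
    total <- total + nf * (nf - 1) / 2
    tab <- table(coarse$labels[s])
    kept <- kept + sum(tab * (tab - 1) / 2)
  }
  if (total == 0) {
    warning("no co-core pairs at the fine level; hierarchy fraction undefined")
    return(NA_real_)
  }
  kept / total
}

#' Parent-daughter graph of core communities across thresholds
#'
#' Builds the hierarchy graph over an ascending sequence of threshold
#' levels: each core at one level ("parent", smaller z0) is connected to
#' every core at the next level ("daughter", larger z0) that shares genes
#' with it, with edge weight equal to the proportion of the daughter's
#' genes coming from that parent. A daughter's incoming weights therefore
#' sum to 1.
#'
#' @param levels Named list mapping threshold value (as name, ascending) to
#'   `core_communities` over a common universe.
#' @return List with `nodes` (data frame: level, core, size) and `edges`
#'   (data frame: parent_level, parent_core, daughter_level, daughter_core,
#'   shared, weight).
#' @export
hierarchy_graph <- function(levels) {
  stopifnot(is.list(levels), length(levels) >= 1L, !is.null(names(levels)))
  lv <- names(levels)
  nodes <- do.call(rbind, lapply(lv, function(z) {
    cc <- levels[[z]]
    data.frame(level = z, core = seq_along(cc$sets), size = cc$sizes)
  }))
  edges <- list()
  if (length(lv) >= 2L) {
    for (li in seq_len(length(lv) - 1L)) {
      parent <- levels[[li]]
      daughter <- levels[[li + 1L]]
      if (!setequal(names(parent$labels), names(daughter$labels))) {
        stop_format("levels '%s' and '%s' cover different gene universes",
                    lv[[li]], lv[[li + 1L]])
      }
      for (d in seq_along(daughter$sets)) {
        ds <- daughter$sets[[d]]
        tab <- table(parent$labels[ds])
        edges[[length(edges) + 1L]] <- data.frame(
          parent_level = lv[[li]],
          parent_core = as.integer(names(tab)),
          daughter_level = lv[[li + 1L]],
          daughter_core = d,
          shared = as.integer(tab),
          weight = as.numeric(tab) / length(ds))
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(parent_level = character(), parent_core = integer(),
               daughter_level = character(), daughter_core = integer(),
               shared = integer(), weight = numeric())
  list(nodes = nodes, edges = edges)
}

#' Gene display order for multi-threshold correlation matrix plots
#'
#' Recursively orders genes so that, at the coarsest level, genes of the
#' largest core come first, and within each core the genes are reordered by
#' the next level's core sizes, and so on through all levels. Ties in size
#' are broken by the lexicographically smallest member; genes inside the
#' finest cores are listed alphabetically.
#'
#' @param levels List of `core_communities` from coarsest to finest, over a
#'   common universe.
#' @return Character vector of gene ids in display order.
#' @export
display_order <- function(levels) {
  stopifnot(is.list(levels), length(levels) >= 1L)
  universe <- names(levels[[1L]]$labels)
  order_rec <- function(genes, depth) {
    if (depth > length(levels)) return(sort(genes))
    labs <- levels[[depth]]$labels[genes]
    blocks <- split(genes, labs)
    first <- vapply(blocks, function(s) min(s), character(1))
    ord <- order(-lengths(blocks), first)
    unlist(lapply(blocks[ord], order_rec, depth = depth + 1L), use.names = FALSE)
  }
  order_rec(universe, 1L)
}

#' Composite RGB image of three co-classification matrices
#'
#' Encodes co-classification at three ascending thresholds into one RGB
#' array: the lowest threshold drives the blue channel, the middle the red
#' channel, and the highest the green channel. A pixel is white where all
#' three proportions are 1 and black where a pair never shares a community
#' at any threshold.
#'
#' @param C_low,C_mid,C_high `coclassification` objects over the same gene
#'   universe (ascending threshold order).
#' @param order Optional gene ordering (character vector), e.g. from
#'   [display_order()].
#' @param file Optional path; when given and the `png` package is
#'   available, the image is also written as a PNG file.
#' @return Numeric array `n x n x 3` with values in `[0, 1]` (R, G, B).
#' @export
composite_matrix_image <- function(C_low, C_mid, C_high, order = NULL,
                                   file = NULL) {
  mats <- list(C_low, C_mid, C_high)
  ids <- lapply(mats, function(x) x$gene_ids)
  if (!setequal(ids[[1L]], ids[[2L]]) || !setequal(ids[[1L]], ids[[3L]])) {
    stop_format("co-classification matrices cover different gene universes")
  }
  if (is.null(order)) order <- ids[[1L]]
  img <- array(0, dim = c(length(order), length(order), 3L))
  img[, , 1L] <- C_mid$C[order, order]   # red:   middle threshold
  img[, , 2L] <- C_high$C[order, order]  # green: highest threshold
  img[, , 3L] <- C_low$C[order, order]   # blue:  lowest threshold
  if (!is.null(file)) {
    if (requireNamespace("png", quietly = TRUE)) {
      png::writePNG(img, target = file)
    } else {
      warning("package 'png' not available; image not written")
    }
  }
  img
}
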