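#' B-spline fuzzy bin weights for one gene's expression profile
#'
#' Distributes each observation's unit mass over `bins` histogram bins using
#' the B-spline basis of the given order. Values are affinely rescaled so
#' the knot span covers `[0, bins - order + 1]` with uniform integer knots;
#' a zero-range (constant) profile maps every observation to position 0.
#' Each row of the returned weight matrix sums to 1 (partition of unity),
#' so the column means form a proper marginal distribution. With
#' `spline_order = 1` the weights reduce to classical hard binning on
#' equal-width bins.
#'
#' @param values Numeric vector of finite expression values (one per
#'   experiment).
#' @param bins Number of bins (default 10).
#' @param spline_order B-spline order (default 3, i.e. quadratic basis).
#' @return Numeric matrix, experiments x bins, rows summing to 1.
#' @export
fuzzy_bin_weights <- function(values, bins = 10L, spline_order = 3L) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  if (!all(is.finite(values))) stop_format("fuzzy_bin_weights: values must be finite")
  bins <- as.integer(bins); spline_order <- as.integer(spline_order)
  if (spline_order < 1L || bins <= spline_order) {
    stop_format("need bins > spline_order >= 1 (got bins=%d, order=%d)", bins, spline_order)
  }
  upper <- bins - spline_order + 1L
  rng <- range(values)
  z <- if (rng[2L] > rng[1L]) (values - rng[1L]) / (rng[2L] - rng[1L]) * upper
       else rep(0, length(values))
  knots <- c(rep(0, spline_order), seq_len(upper - 1L), rep(upper, spline_order))
  W <- splines::splineDesign(knots, z, ord = spline_order)
  # guard the right boundary: a row that received no mass belongs to the last bin
  s <- rowSums(W)
  if (any(s < 0.5)) {
    fix <- s < 0.5
    W[fix, ] <- 0
    W[fix, bins] <- 1
  }
  W
}

#' Mutual information between two fuzzy-binned profiles
#'
#' Plug-in estimate in bits. Marginals are column means of the weight
#' matrices; the joint is the experiment-averaged outer product of the two
#' weight rows. Cells with zero joint mass contribute nothing. Tiny negative
#' round-off is clipped to zero.
#'
#' @param weights_i,weights_j Weight matrices from [fuzzy_bin_weights()]
#'   with the same number of experiment rows.
#' @return Mutual information in bits (non-negative scalar).
#' @export
mutual_information <- function(weights_i, weights_j) {
  if (nrow(weights_i) != nrow(weights_j)) {
    stop_format("weight matrices disagree on experiment count (%d vs %d)",
                nrow(weights_i), nrow(weights_j))
  }
  E <- nrow(weights_i)
  P <- crossprod(weights_i, weights_j) / E
  pa <- colSums(weights_i) / E
  pb <- colSums(weights_j) / E
  den <- outer(pa, pb)
  pos <- P > 0
  I <- sum(P[pos] * log2(P[pos] / den[pos]))
  max(I, 0)
}

# Marginal entropy (bits) of a fuzzy-binned profile.
marginal_entropy <- function(weights) {
  p <- colSums(weights) / nrow(weights)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Pairwise mutual-information matrix
#'
#' Computes MI for every gene pair of an expression matrix. The diagonal
#' holds each gene's marginal entropy; background statistics downstream
#' exclude it.
#'
#' @param expr Numeric matrix, genes x experiments, with row and column
#'   names (see [read_expression_matrix()]).
#' @param bins,spline_order Binning options, see [fuzzy_bin_weights()].
#' @return An `mi_matrix`: list with `mi` (symmetric matrix, bits),
#'   `gene_ids`, `bins`, `spline_order`.
#' @export
mi_matrix <- function(expr, bins = 10L, spline_order = 3L) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 2L) stop_format("need at least 2 experiments to estimate distributions")
  gene_ids <- rownames(expr)
  check_gene_ids(gene_ids)
  n <- nrow(expr)
  E <- ncol(expr)
  W <- lapply(seq_len(n), function(i) fuzzy_bin_weights(expr[i, ], bins, spline_order))
  marg <- lapply(W, function(w) colSums(w) / E)
  I <- matrix(0, n, n, dimnames = list(gene_ids, gene_ids))
  for (i in seq_len(n)) {
    wi <- W[[i]]; pa <- marg[[i]]
    for (j in seq_len(n)) {
      if (j <= i) next
      P <- crossprod(wi, W[[j]]) / E
      den <- outer(pa, marg[[j]])
      pos <- P > 0
      v <- sum(P[pos] * log2(P[pos] / den[pos]))
      I[i, j] <- I[j, i] <- max(v, 0)
    }
    p <- pa[pa > 0]
    I[i, i] <- -sum(p * log2(p))
  }
  structure(list(mi = I, gene_ids = gene_ids,
                 bins = bins, spline_order = spline_order),
            class = "mi_matrix")
}

#' Per-gene background Z-scores of mutual information
#'
#' Each MI value is compared to the empirical distribution of MI between
#' each of its genes and all other genes (diagonal self-entropies
#' excluded), assumed normal. Z-scores below zero are set to zero. A
#' degenerate background (sigma = 0) yields Z = 0.
#'
#' @param mi An `mi_matrix` (or bare symmetric MI matrix).
#' @return List with `z` (matrix; `z[i, j]` is gene i's background Z for
#'   pair (i, j), so the pair's two scores are `z[i, j]` and `z[j, i]`),
#'   `mean` and `sd` (per-gene background statistics, population sigma).
#' @export
background_z <- function(mi) {
  I <- if (inherits(mi, "mi_matrix")) mi$mi else mi
  n <- nrow(I)
  if (n < 3L) stop_format("background Z-scores need at least 3 genes")
  off <- I
  diag(off) <- NA_real_
  mu <- rowMeans(off, na.rm = TRUE)
  # population sigma over the n-1 off-diagonal entries of each row
  sq <- rowMeans(off^2, na.rm = TRUE)
  sigma <- sqrt(pmax(sq - mu^2, 0))
  Z <- (I - mu) / ifelse(sigma > 0, sigma, Inf)
  Z[Z < 0] <- 0
  diag(Z) <- 0
  list(z = Z, mean = mu, sd = sigma)
}

#' CLR relatedness matrix
#'
#' Combines the two background Z-scores of each pair into a single
#' non-negative relatedness value. The default joint combiner is
#' `f = sqrt(Zi^2 + Zj^2)`; `"max"` takes the larger score.
#'
#' @param mi An `mi_matrix`.
#' @param combine Combination rule, `"joint"` (default) or `"max"`.
#' @return A `clr_relatedness`: list with `f` (symmetric matrix, zero
#'   diagonal), `gene_ids`, `combine`.
#' @export
clr_relatedness <- function(mi, combine = c("joint", "max")) {
  combine <- match.arg(combine)
  bz <- background_z(mi)
  Z <- bz$z
  f <- switch(combine,
              joint = sqrt(Z^2 + t(Z)^2),
              max = pmax(Z, t(Z)))
  diag(f) <- 0
  structure(list(f = f, gene_ids = rownames(f), combine = combine),
            class = "clr_relatedness")
}

#' Threshold a relatedness matrix into an unweighted network
#'
#' Links every pair whose relatedness strictly exceeds `z0` ("exceeds"
#' rule; set `strict = FALSE` to also link ties).
#'
#' @param rel A `clr_relatedness` (or bare symmetric matrix).
#' @param z0 Non-negative relatedness threshold.
#' @param strict Use strict inequality `f > z0` (default TRUE).
#' @return A `threshold_network`: list with `gene_ids`, `adjacency`
#'   (0/1 integer matrix, zero diagonal), `degrees`, `m` (link count), `z0`.
#' @export
threshold_network <- function(rel, z0, strict = TRUE) {
  stopifnot(z0 >= 0)
  f <- if (inherits(rel, "clr_relatedness")) rel$f else rel
  A <- if (strict) (f > z0) else (f >= z0)
  storage.mode(A) <- "integer"
  diag(A) <- 0L
  as_threshold_network(A, z0 = z0)
}

#' Construct a threshold network from an adjacency matrix
#'
#' @param A Symmetric 0/1 matrix with gene ids as dimnames and zero
#'   diagonal.
#' @param z0 Threshold to record (metadata).
#' @return A `threshold_network`.
#' @export
as_threshold_network <- function(A, z0 = NA_real_) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (is.null(rownames(A))) {
    rownames(A) <- colnames(A) <- paste0("g", seq_len(nrow(A)))
  }
  storage.mode(A) <- "integer"
  if (!identical(A, t(A))) stop_format("adjacency matrix must be symmetric")
  if (any(diag(A) != 0L)) stop_format("adjacency matrix must have a zero diagonal")
  if (any(A != 0L & A != 1L)) stop_format("adjacency entries must be 0 or 1")
  degrees <- rowSums(A)
  structure(list(gene_ids = rownames(A), adjacency = A,
                 degrees = degrees, m = sum(degrees) / 2, z0 = z0),
            class = "threshold_network")
}

#' @export
print.threshold_network <- function(x, ...) {
  cat(sprintf("threshold_network: %d genes, %d links (z0 = %s)\n",
              length(x$gene_ids), x$m, format(x$z0)))
  invisible(x)
}

#' Largest-component scan over a threshold grid
#'
#' For each threshold in `z0_grid`, thresholds the relatedness matrix and
#' records the size of the largest connected component and the number of
#' components. The largest-component size is non-increasing in `z0`.
#'
#' @param rel A `clr_relatedness` (or bare symmetric matrix).
#' @param z0_grid Ascending numeric vector of thresholds.
#' @return Data frame with columns `z0`, `largest_component`,
#'   `n_components`, `n_links`.
#' @export
component_scan <- function(rel, z0_grid) {
  if (length(z0_grid) == 0L) stop_format("empty threshold grid")
  if (is.unsorted(z0_grid)) stop_format("threshold grid must be ascending")
  rows <- lapply(z0_grid, function(z0) {
    net <- threshold_network(rel, z0)
    g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
    comp <- igraph::components(g)
    data.frame(z0 = z0,
               largest_component = max(comp$csize),
               n_components = comp$no,
               n_links = net$m)
  })
  do.call(rbind, rows)
}
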