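#' Specification for two-level hierarchical synthetic expression data
#'
#' Defines a latent-factor model with planted two-level group structure:
#' genes in the same top-level group share a group signal with weight `a`,
#' genes in the same subgroup additionally share a subgroup signal with
#' weight `b`, and every value carries independent residual noise
#' `sigma_eps`. All signals are standard normal across experiments, so a
#' within-subgroup pair has covariance `a^2 + b^2`, a within-group
#' cross-subgroup pair `a^2`, and cross-group pairs 0. The defaults (4
#' groups of 3 subgroups of 10 genes, 200 experiments, a = b = 1,
#' sigma_eps = 0.5) give a clearly detectable two-level hierarchy and are
#' the reference setting used throughout the test suite.
#'
#' @param groups Number of top-level groups.
#' @param subgroups Subgroups per group.
#' @param genes_per Genes per subgroup.
#' @param experiments Number of experiments E.
#' @param a Top-level signal weight.
#' @param b Subgroup signal weight.
#' @param sigma_eps Residual noise standard deviation.
#' @param seed Integer seed.
#' @return A `hier_spec` list.
#' @export
hier_spec <- function(groups = 4L, subgroups = 3L, genes_per = 10L,
                      experiments = 200L, a = 1, b = 1, sigma_eps = 0.5,
                      seed = 1L) {
  stopifnot(groups >= 1L, subgroups >= 1L, genes_per >= 1L,
            experiments >= 2L, a >= 0, b >= 0, sigma_eps >= 0)
  structure(list(groups = as.integer(groups),
                 subgroups = as.integer(subgroups),
                 genes_per = as.integer(genes_per),
                 experiments = as.integer(experiments),
                 a = a, b = b, sigma_eps = sigma_eps,
                 seed = as.integer(seed)),
            class = "hier_spec")
}

#' Simulate expression data with planted two-level structure
#'
#' Draws `x_ge = a * S[group(g), e] + b * T[subgroup(g), e] + eps_ge`, with
#' `S`, `T` standard normal latent signals and
#' `eps ~ Normal(0, sigma_eps)`, all independent. Bit-reproducible from the
#' spec's seed.
#'
#' @param spec A `hier_spec`.
#' @return List with `expr` (genes x experiments matrix with dimnames) and
#'   `truth` (data frame: gene, group, subgroup).
#' @export
simulate_hier_expression <- function(spec) {
  stopifnot(inherits(spec, "hier_spec"))
  n_sub <- spec$groups * spec$subgroups
  n_genes <- n_sub * spec$genes_per
  E <- spec$experiments
  group_of <- rep(seq_len(spec$groups), each = spec$subgroups * spec$genes_per)
  sub_of <- rep(seq_len(n_sub), each = spec$genes_per)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  exp_ids <- sprintf("e%03d", seq_len(E))
  expr <- with_seed(spec$seed, {
    S <- matrix(stats::rnorm(spec$groups * E), spec$groups, E)
    T_sig <- matrix(stats::rnorm(n_sub * E), n_sub, E)
    eps <- matrix(stats::rnorm(n_genes * E, sd = spec$sigma_eps), n_genes, E)
    spec$a * S[group_of, , drop = FALSE] +
      spec$b * T_sig[sub_of, , drop = FALSE] + eps
  })
  dimnames(expr) <- list(gene_ids, exp_ids)
  truth <- data.frame(gene = gene_ids, group = group_of, subgroup = sub_of)
  list(expr = expr, truth = truth)
}

#' Simulate replicated experiments around a hierarchical base dataset
#'
#' Generates a base dataset with [simulate_hier_expression()] and expands
#' every base experiment into `replicates` replicate columns, each the base
#' value plus independent `Normal(0, sigma_rep)` measurement error. The
#' returned replicate map feeds [replicate_summary()].
#'
#' @param spec A `hier_spec`.
#' @param replicates Replicate columns per base experiment (>= 3 to satisfy
#'   the retention rule downstream; default 3, the typical low replication
#'   of expression compendia).
#' @param sigma_rep Measurement error standard deviation (default 1, a
#'   typical replicate-to-replicate spread for log2 microarray
#'   intensities).
#' @return List with `expr` (genes x (E * replicates) matrix), `reps`
#'   (named list base id -> replicate column ids), `base` (the unreplicated
#'   base matrix) and `truth`.
#' @export
simulate_replicates <- function(spec, replicates = 3L, sigma_rep = 1) {
  stopifnot(inherits(spec, "hier_spec"), sigma_rep >= 0)
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop_format("need at least 1 replicate")
  sim <- simulate_hier_expression(spec)
  base <- sim$expr
  E <- ncol(base)
  rep_ids <- lapply(colnames(base), function(b) {
    sprintf("%s_r%d", b, seq_len(replicates))
  })
  names(rep_ids) <- colnames(base)
  expr <- with_seed(derive_seed(spec$seed, 7L), {
    noise <- matrix(stats::rnorm(nrow(base) * E * replicates, sd = sigma_rep),
                    nrow(base), E * replicates)
    base[, rep(seq_len(E), each = replicates), drop = FALSE] + noise
  })
  dimnames(expr) <- list(rownames(base), unlist(rep_ids, use.names = FALSE))
  list(expr = expr, reps = rep_ids, base = base, truth = sim$truth)
}

#' Planted-partition random graph
#'
#' Independent Bernoulli links with probability `p_in` inside blocks and
#' `p_out` between blocks; the result is a simple graph wrapped as a
#' `threshold_network`.
#'
#' @param sizes Integer vector of block sizes.
#' @param p_in Within-block link probability.
#' @param p_out Between-block link probability, `p_out < p_in`.
#' @param seed Integer seed.
#' @return List with `network` (a `threshold_network`) and `truth` (named
#'   integer block label per node).
#' @export
planted_partition_graph <- function(sizes, p_in, p_out, seed = 1L) {
  stopifnot(all(sizes >= 1L), p_out >= 0, p_in <= 1, p_out < p_in)
  n <- sum(sizes)
  block <- rep(seq_along(sizes), sizes)
  ids <- sprintf("n%03d", seq_len(n))
  A <- matrix(0L, n, n, dimnames = list(ids, ids))
  probs <- ifelse(outer(block, block, "=="), p_in, p_out)
  draws <- with_seed(seed, matrix(stats::runif(n * n), n, n))
  up <- upper.tri(A)
  A[up] <- as.integer(draws[up] < probs[up])
  A <- A + t(A)
  list(network = as_threshold_network(A),
       truth = stats::setNames(block, ids))
}
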