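#' Hypergeometric enrichment probability
#'
#' Probability that a community of size `n`, drawn from a universe of `N`
#' genes, shares at least `k` genes with a term of size `m` (upper tail,
#' the standard enrichment test). `mode = "point"` instead returns the
#' probability of exactly `k` shared genes. Both are computed through the
#' log-space hypergeometric routines, so values far below 1e-45 remain
#' accurate.
#'
#' @param N Universe size.
#' @param n Community size.
#' @param m Term size.
#' @param k Overlap, `0 <= k <= min(n, m)`.
#' @param mode `"tail"` (default, P(X >= k)) or `"point"` (P(X = k)).
#' @return Probability in `[0, 1]`.
#' @export
hypergeom_tail <- function(N, n, m, k, mode = c("tail", "point")) {
  mode <- match.arg(mode)
  if (any(c(N, n, m, k) < 0) || k > min(n, m) || n > N || m > N) {
    stop_format("inconsistent hypergeometric counts (N=%s n=%s m=%s k=%s)",
                N, n, m, k)
  }
  if (mode == "point") return(stats::dhyper(k, m, N - m, n))
  stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg correction with explicit family size
#'
#' Orders the p-values ascending and multiplies the i-th smallest by
#' `M / i`, where `M` is the number of hypotheses in the family (which may
#' exceed the number of p-values supplied). The default `"literal"` variant
#' applies exactly this rank scaling; `"step_up"` additionally enforces
#' monotonicity with the usual cumulative minimum from the largest rank
#' down, and caps at 1. Input order is restored in the output.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param M Family size, `M >= length(p)`.
#' @param variant `"literal"` (default) or `"step_up"`.
#' @return Numeric vector of corrected p-values, same order as `p`.
#' @export
bh_correct <- function(p, M = length(p), variant = c("literal", "step_up")) {
  variant <- match.arg(variant)
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1)) stop_format("p-values must lie in [0, 1]")
  if (M < length(p)) stop_format("family size M must be >= length(p)")
  ord <- order(p)
  ranks <- seq_along(p)
  corrected_sorted <- p[ord] * M / ranks
  if (variant == "step_up") {
    corrected_sorted <- rev(cummin(rev(corrected_sorted)))
    corrected_sorted <- pmin(corrected_sorted, 1)
  }
  out <- numeric(length(p))
  out[ord] <- corrected_sorted
  out
}

#' Term enrichment of core communities
#'
#' Tests every core community of at least `min_size` genes against all
#' annotation terms with the upper-tail hypergeometric test, corrects
#' within each community over the full family of `M` terms
#' (Benjamini-Hochberg), and keeps results that are significant
#' (`p_corrected < alpha`) and positively enriched (observed overlap above
#' its expectation `n * m / N`). Depletions, however extreme, are never
#' reported.
#'
#' @param cores A `core_communities` (or a `network_partition`, whose
#'   communities are then tested).
#' @param annotations An `annotation_set` from [read_go_annotations()].
#' @param alpha Significance level on corrected p-values (default 0.05).
#' @param min_size Smallest community size tested (default 10, below which
#'   modularity optimization cannot resolve communities reliably).
#' @param universe_size Total gene count `N`; defaults to the number of
#'   genes in the core set's universe.
#' @param bh_variant Passed to [bh_correct()].
#' @return Data frame sorted by corrected p-value with columns `community`,
#'   `p_corrected`, `p_raw`, `rank`, `term_id`, `com_size`, `term_size`,
#'   `in_common`, `expected`, `description`.
#' @export
enrich_communities <- function(cores, annotations, alpha = 0.05,
                               min_size = 10L, universe_size = NULL,
                               bh_variant = "literal") {
  stopifnot(inherits(annotations, "annotation_set"))
  if (length(annotations$terms) == 0L) stop_format("annotation set is empty")
  sets <- community_sets(cores)
  N <- if (is.null(universe_size)) length(unlist(sets, use.names = FALSE)) else universe_size
  M <- annotations$n_terms
  term_ids <- names(annotations$terms)
  rows <- list()
  for (comm in seq_along(sets)) {
    genes <- sets[[comm]]
    n <- length(genes)
    if (n < min_size) next
    m_sizes <- lengths(annotations$terms)
    k_vals <- vapply(annotations$terms, function(tg) length(intersect(tg, genes)),
                     integer(1))
    p_raw <- vapply(seq_along(term_ids), function(t) {
      hypergeom_tail(N, n, m_sizes[[t]], k_vals[[t]])
    }, numeric(1))
    p_corr <- bh_correct(p_raw, M = M, variant = bh_variant)
    ranks <- rank(p_raw, ties.method = "first")
    expected <- n * m_sizes / N
    keep <- p_corr < alpha & k_vals > expected
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      community = comm,
      p_corrected = p_corr[keep],
      p_raw = p_raw[keep],
      rank = ranks[keep],
      term_id = term_ids[keep],
      com_size = n,
      term_size = m_sizes[keep],
      in_common = k_vals[keep],
      expected = expected[keep],
      description = unname(annotations$descriptions[term_ids[keep]]),
      row.names = NULL)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(community = integer(), p_corrected = numeric(),
               p_raw = numeric(), rank = integer(), term_id = character(),
               com_size = integer(), term_size = integer(),
               in_common = integer(), expected = numeric(),
               description = character())
  out[order(out$p_corrected, out$p_raw), , drop = FALSE]
}

# Communities as a list of gene-id sets, from cores or a partition.
community_sets <- function(x) {
  if (inherits(x, "core_communities")) return(x$sets)
  mem <- membership_vector(x)
  unname(split(names(mem), mem))
}

#' Operon-retention permutation test
#'
#' Observed statistic: the fraction of multi-gene operons whose members all
#' fall in a single community of the partition. The null distribution comes
#' from randomly permuting the gene-to-community assignment (community
#' sizes preserved) `n_perm` times; the empirical p-value uses the +1
#' correction `(1 + #[null >= observed]) / (n_perm + 1)` so it is never 0.
#'
#' @param partition A `network_partition` or named label vector.
#' @param operons Named list operon id -> member gene ids (see
#'   [read_operons()]); members must be in the partition's universe.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return An `operon_test`: list with `observed`, `null` (numeric vector),
#'   `p_value`, `n_operons` (multi-gene operons tested).
#' @export
operon_retention <- function(partition, operons, n_perm = 1000L, seed = 1L) {
  mem <- membership_vector(partition)
  multi <- operons[lengths(operons) >= 2L]
  if (length(multi) == 0L) stop_format("no multi-gene operon to test")
  missing_genes <- setdiff(unlist(multi, use.names = FALSE), names(mem))
  if (length(missing_genes) > 0L) {
    stop_format("operon gene '%s' is not in the partition universe", missing_genes[[1L]])
  }
  retained <- function(labels) {
    mean(vapply(multi, function(genes) {
      length(unique(labels[genes])) == 1L
    }, logical(1)))
  }
  observed <- retained(mem)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    perm <- stats::setNames(sample(unname(mem)), names(mem))
    retained(perm)
  }, numeric(1)))
  p <- (1 + sum(null >= observed)) / (n_perm + 1)
  structure(list(observed = observed, null = null, p_value = p,
                 n_operons = length(multi)),
            class = "operon_test")
}

#' @export
print.operon_test <- function(x, ...) {
  cat(sprintf("operon retention: observed %.4f over %d operons, permutation p = %.4g\n",
              x$observed, x$n_operons, x$p_value))
  invisible(x)
}
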