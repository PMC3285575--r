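# Shared fixtures: small graphs and hand-built objects, all generated in code.

# Two triangles (a,b,c) and (d,e,f) joined by the bridge c-d.
bridged_triangles <- function() {
  ids <- letters[1:6]
  A <- matrix(0L, 6, 6, dimnames = list(ids, ids))
  edges <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4))
  for (i in seq_len(nrow(edges))) {
    A[edges[i, 1], edges[i, 2]] <- 1L
    A[edges[i, 2], edges[i, 1]] <- 1L
  }
  as_threshold_network(A)
}

complete_graph <- function(n) {
  ids <- paste0("v", seq_len(n))
  A <- matrix(1L, n, n, dimnames = list(ids, ids))
  diag(A) <- 0L
  as_threshold_network(A)
}

# Two disconnected cliques of size k each.
clique_pair <- function(k = 4L) {
  n <- 2L * k
  ids <- paste0("v", seq_len(n))
  A <- matrix(0L, n, n, dimnames = list(ids, ids))
  A[seq_len(k), seq_len(k)] <- 1L
  A[(k + 1):n, (k + 1):n] <- 1L
  diag(A) <- 0L
  as_threshold_network(A)
}

# Erdos-Renyi graph with at least one edge, reproducible from seed.
random_graph <- function(n, p, seed) {
  ids <- paste0("v", seq_len(n))
  A <- matrix(0L, n, n, dimnames = list(ids, ids))
  up <- upper.tri(A)
  A[up] <- withr::with_seed(seed, as.integer(stats::runif(sum(up)) < p))
  A <- A + t(A)
  if (sum(A) == 0L) {
    A[1, 2] <- A[2, 1] <- 1L
  }
  as_threshold_network(A)
}

# Build a core_communities object directly from a list of gene sets.
make_cores <- function(sets, tau = 1) {
  ord <- order(-lengths(sets), vapply(sets, min, character(1)))
  sets <- unname(sets[ord])
  genes <- unlist(sets, use.names = FALSE)
  labels <- integer(length(genes))
  names(labels) <- genes
  for (i in seq_along(sets)) labels[sets[[i]]] <- i
  structure(list(sets = sets, labels = labels, tau = tau, sizes = lengths(sets)),
            class = "core_communities")
}

# Build a coclassification object from a proportion matrix and ensemble size.
make_coclass <- function(C, R) {
  structure(list(C = C, counts = round(C * R), R = R, gene_ids = rownames(C)),
            class = "coclassification")
}

# Membership vector as a canonical list of sorted gene sets (label-free
# comparison of partitions).
canonical_sets <- function(mem) {
  s <- lapply(split(names(mem), mem), sort)
  unname(s[order(vapply(s, `[[`, character(1), 1L))])
}

# Classical hard-binned plug-in MI estimate (independent oracle).
hard_binned_mi <- function(x, y, bins = 10L) {
  bin_of <- function(v) {
    r <- range(v)
    if (r[2] == r[1]) return(rep(1L, length(v)))
    pmin(floor((v - r[1]) / (r[2] - r[1]) * bins) + 1L, bins)
  }
  tab <- table(factor(bin_of(x), seq_len(bins)),
               factor(bin_of(y), seq_len(bins))) / length(x)
  px <- rowSums(tab)
  py <- colSums(tab)
  s <- 0
  for (a in seq_len(bins)) {
    for (b in seq_len(bins)) {
      if (tab[a, b] > 0) s <- s + tab[a, b] * log2(tab[a, b] / (px[a] * py[b]))
    }
  }
  as.numeric(s)
}

# Reference two-level synthetic dataset shared by recovery tests; computed
# once per test run.
reference_pipeline <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- hier_spec(seed = 1L)
    sim <- simulate_hier_expression(spec)
    mi <- mi_matrix(sim$expr)
    rel <- clr_relatedness(mi)
    cache <<- list(spec = spec, sim = sim, mi = mi, rel = rel)
    cache
  }
})
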