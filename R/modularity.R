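#' Modularity of a partition
#'
#' `Q` is the fraction of links inside communities minus the fraction
#' expected when the degree sequence is kept but links are placed at
#' random: `Q = (1/2m) sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j)`.
#'
#' @param network A `threshold_network` with at least one link.
#' @param partition A `network_partition` or named label vector covering
#'   exactly the network's genes.
#' @return Modularity Q in `[-1, 1)`.
#' @export
modularity_q <- function(network, partition) {
  stopifnot(inherits(network, "threshold_network"))
  if (network$m < 1) stop_format("modularity is undefined for a network with no links")
  mem <- membership_vector(partition)
  if (!setequal(names(mem), network$gene_ids) ||
      length(mem) != length(network$gene_ids)) {
    stop_format("partition must cover exactly the network's genes")
  }
  mem <- mem[network$gene_ids]
  A <- network$adjacency
  k <- network$degrees
  m <- network$m
  q <- 0
  for (lab in unique(mem)) {
    idx <- which(mem == lab)
    e_c <- sum(A[idx, idx]) / 2
    K_c <- sum(k[idx])
    q <- q + e_c / m - (K_c / (2 * m))^2
  }
  q
}

#' Generalized modularity matrix of a node group
#'
#' For the full network this is `B = A - k k' / (2m)` (rows sum to zero).
#' For a proper subgroup the diagonal is corrected by the group row sums so
#' that splitting the group changes total modularity by `s' B s / (4m)` for
#' a sign vector `s`.
#'
#' @param network A `threshold_network`.
#' @param group Integer or character indices of the group (default: all).
#' @return Symmetric numeric matrix.
#' @export
modularity_matrix <- function(network, group = NULL) {
  stopifnot(inherits(network, "threshold_network"))
  if (network$m < 1) stop_format("modularity matrix is undefined for a network with no links")
  if (is.null(group)) group <- seq_along(network$gene_ids)
  if (is.character(group)) group <- match(group, network$gene_ids)
  A <- network$adjacency
  k <- network$degrees
  m <- network$m
  Bg <- A[group, group, drop = FALSE] - outer(k[group], k[group]) / (2 * m)
  if (length(group) < length(network$gene_ids)) {
    # subdivision form: subtract each row's sum over the group on the
    # diagonal, so s' Bg s / (4m) is the modularity change of a split
    diag(Bg) <- diag(Bg) - rowSums(Bg)
  }
  Bg
}

# Leading eigenpair of a symmetric matrix: dense solver for small groups,
# shifted power iteration (seeded start) for large ones.
leading_eigen <- function(B, seed, dense_limit = 64L, tol = 1e-10, max_iter = 10000L) {
  n <- nrow(B)
  if (n <= dense_limit) {
    es <- eigen(B, symmetric = TRUE)
    return(list(value = es$values[[1L]], vector = es$vectors[, 1L]))
  }
  shift <- max(rowSums(abs(B)))  # Gershgorin bound: B + shift*I is PSD
  v <- with_seed(seed, stats::rnorm(n))
  v <- v / sqrt(sum(v^2))
  lambda_old <- Inf
  for (iter in seq_len(max_iter)) {
    w <- as.vector(B %*% v) + shift * v
    nw <- sqrt(sum(w^2))
    if (nw == 0) break
    v <- w / nw
    lambda <- sum(v * (B %*% v))
    if (abs(lambda - lambda_old) < tol) break
    lambda_old <- lambda
  }
  list(value = sum(v * (B %*% v)), vector = v)
}

# Kernighan-Lin refinement of a sign vector s maximizing s' B s.
# Sweeps in seeded random order; every node flips exactly once per sweep and
# the best prefix is kept; repeats until no sweep improves.
refine_signs <- function(B, s, seed, tol = 1e-12) {
  n <- length(s)
  g <- as.vector(B %*% s)
  sweep_no <- 0L
  repeat {
    sweep_no <- sweep_no + 1L
    order_v <- with_seed(derive_seed(seed, sweep_no), sample.int(n))
    s_sweep <- s
    g_sweep <- g
    gains <- numeric(n)
    cum <- 0
    best <- 0
    best_idx <- 0L
    for (pos in seq_len(n)) {
      i <- order_v[[pos]]
      delta <- -4 * s_sweep[[i]] * (g_sweep[[i]] - B[i, i] * s_sweep[[i]])
      cum <- cum + delta
      g_sweep <- g_sweep - 2 * s_sweep[[i]] * B[, i]
      s_sweep[[i]] <- -s_sweep[[i]]
      gains[[pos]] <- cum
      if (cum > best + tol) {
        best <- cum
        best_idx <- pos
      }
    }
    if (best_idx == 0L) break
    # replay the accepted prefix
    for (pos in seq_len(best_idx)) {
      i <- order_v[[pos]]
      g <- g - 2 * s[[i]] * B[, i]
      s[[i]] <- -s[[i]]
    }
  }
  s
}

#' Split one group by the leading eigenvector of its modularity matrix
#'
#' Computes the leading eigenpair of the generalized modularity matrix
#' restricted to `group`. If the leading eigenvalue is non-positive the
#' group is indivisible. Otherwise nodes are split by eigenvector sign
#' (entries within 1e-12 of zero go to the positive side), the bipartition
#' is refined by Kernighan-Lin sign flips, and the split is accepted only
#' if it increases modularity.
#'
#' @param network A `threshold_network`.
#' @param group Indices (integer) or gene ids (character) of the group;
#'   at least 2 nodes.
#' @param seed Integer seed controlling refinement sweep order.
#' @param tol Acceptance tolerance on the modularity gain.
#' @return List with `divisible` (logical), `groups` (list of two integer
#'   index vectors when divisible), `dq` (modularity gain), `eigenvalue`.
#' @export
leading_split <- function(network, group, seed, tol = 1e-10) {
  if (is.character(group)) group <- match(group, network$gene_ids)
  if (length(group) < 2L) stop_format("leading_split needs a group of at least 2 nodes")
  B <- modularity_matrix(network, group)
  le <- leading_eigen(B, seed = derive_seed(seed, 1L))
  indivisible <- list(divisible = FALSE, groups = NULL, dq = 0, eigenvalue = le$value)
  if (le$value <= tol) return(indivisible)
  s <- ifelse(le$vector >= -1e-12, 1, -1)
  s <- refine_signs(B, s, seed = derive_seed(seed, 2L))
  dq <- as.numeric(t(s) %*% B %*% s) / (4 * network$m)
  if (dq <= tol || length(unique(s)) < 2L) return(indivisible)
  list(divisible = TRUE,
       groups = list(group[s > 0], group[s < 0]),
       dq = dq, eigenvalue = le$value)
}

#' Partition a network by recursive bisection with final tuning
#'
#' Repeatedly applies [leading_split()] until no group is divisible, then
#' applies [final_tune()] to the multiway partition. Stochastic only
#' through the seeded node orders of the refinement sweeps: identical seeds
#' give identical partitions, different seeds may differ (the variability
#' the ensemble analysis consumes). Isolated nodes become their own
#' communities.
#'
#' @param network A `threshold_network`.
#' @param seed Integer seed.
#' @return A `network_partition`: list with `membership` (named integer
#'   labels, contiguous from 0), `q` (cached modularity), `n_communities`,
#'   `seed`.
#' @export
partition_network <- function(network, seed = 1L) {
  stopifnot(inherits(network, "threshold_network"))
  n <- length(network$gene_ids)
  if (network$m < 1) {
    warning("network has no links; returning all-singleton partition")
    mem <- stats::setNames(seq_len(n) - 1L, network$gene_ids)
    return(structure(list(membership = mem, q = NA_real_,
                          n_communities = n, seed = seed),
                     class = "network_partition"))
  }
  isolated <- which(network$degrees == 0)
  active <- setdiff(seq_len(n), isolated)
  mem <- integer(n)
  groups <- list(active)
  done <- list()
  counter <- 0L
  while (length(groups) > 0L) {
    g <- groups[[1L]]
    groups <- groups[-1L]
    counter <- counter + 1L
    if (length(g) < 2L) {
      done[[length(done) + 1L]] <- g
      next
    }
    sp <- leading_split(network, g, seed = derive_seed(seed, counter))
    if (sp$divisible) {
      groups <- c(groups, sp$groups)
    } else {
      done[[length(done) + 1L]] <- g
    }
  }
  lab <- 0L
  for (g in done) {
    mem[g] <- lab
    lab <- lab + 1L
  }
  for (i in isolated) {
    mem[i] <- lab
    lab <- lab + 1L
  }
  names(mem) <- network$gene_ids
  tuned <- final_tune(network, mem, seed = derive_seed(seed, 1000003L))
  tuned$partition$seed <- seed
  tuned$partition
}

#' Kernighan-Lin style final tuning of a multiway partition
#'
#' Repeated sweeps in seeded random node order. Within a sweep every node
#' is moved exactly once to its best target (any existing community or a
#' new singleton; the locally best move may decrease Q), and the sweep's
#' best prefix state is kept. After each sweep, pairs of communities whose
#' merger increases Q are merged greedily. The two phases alternate until
#' neither yields an improvement, so Q never decreases overall. Node moves
#' and merges together remove the bias of the strictly bisective
#' recursion, which cannot reunite groups separated by an early cut.
#'
#' @param network A `threshold_network` with at least one link.
#' @param partition A `network_partition` or named label vector.
#' @param seed Integer seed for sweep orders.
#' @param tol Improvement tolerance ending the sweep loop.
#' @return List with `partition` (tuned `network_partition`) and `trace`
#'   (per-sweep moves with their incremental `dq`, the accepted prefix
#'   length, and Q before/after).
#' @export
final_tune <- function(network, partition, seed = 1L, tol = 1e-10) {
  stopifnot(inherits(network, "threshold_network"))
  if (network$m < 1) stop_format("final_tune needs a network with links")
  mem <- membership_vector(partition)
  mem <- mem[network$gene_ids]
  A <- network$adjacency
  k <- network$degrees
  m <- network$m
  n <- length(mem)
  labels <- as.integer(factor(mem)) - 1L
  K <- tapply(k, labels, sum)
  K_tot <- stats::setNames(as.numeric(K), names(K))
  q_before <- modularity_q(network, stats::setNames(labels, network$gene_ids))
  sweeps <- list()
  sweep_no <- 0L
  repeat {
    sweep_no <- sweep_no + 1L
    order_v <- with_seed(derive_seed(seed, sweep_no), sample.int(n))
    lab_sweep <- labels
    K_sweep <- K_tot
    moves <- vector("list", n)
    cum <- 0
    best <- 0
    best_idx <- 0L
    next_label <- max(lab_sweep) + 1L
    for (pos in seq_len(n)) {
      v <- order_v[[pos]]
      a <- lab_sweep[[v]]
      nbr <- which(A[v, ] == 1L)
      d_v <- table(factor(lab_sweep[nbr], levels = names(K_sweep)))
      d_v <- stats::setNames(as.numeric(d_v), names(d_v))
      a_key <- as.character(a)
      size_a <- sum(lab_sweep == a)
      targets <- setdiff(names(K_sweep)[K_sweep > 0 | names(K_sweep) %in%
                                          as.character(lab_sweep)], a_key)
      targets <- unique(c(targets, if (size_a > 1L) "new"))
      if (length(targets) == 0L) {
        moves[[pos]] <- list(node = v, target = a, dq = 0)
        next
      }
      d_va <- d_v[[a_key]]
      best_dq <- -Inf
      best_t <- NULL
      for (t in targets) {
        if (t == "new") {
          d_vb <- 0
          K_b <- 0
        } else {
          d_vb <- d_v[[t]]
          K_b <- K_sweep[[t]]
        }
        dq <- (d_vb - d_va) / m -
          k[[v]] * (K_b - K_sweep[[a_key]] + k[[v]]) / (2 * m^2)
        if (dq > best_dq + 1e-15) {
          best_dq <- dq
          best_t <- t
        }
      }
      if (best_t == "new") {
        b <- next_label
        next_label <- next_label + 1L
        K_sweep[[as.character(b)]] <- 0
      } else {
        b <- as.integer(best_t)
      }
      b_key <- as.character(b)
      lab_sweep[[v]] <- b
      K_sweep[[a_key]] <- K_sweep[[a_key]] - k[[v]]
      K_sweep[[b_key]] <- K_sweep[[b_key]] + k[[v]]
      cum <- cum + best_dq
      moves[[pos]] <- list(node = v, target = b, dq = best_dq)
      if (cum > best + tol) {
        best <- cum
        best_idx <- pos
      }
    }
    move_df <- data.frame(
      node = vapply(moves, function(mv) mv$node, numeric(1)),
      target = vapply(moves, function(mv) mv$target, numeric(1)),
      dq = vapply(moves, function(mv) mv$dq, numeric(1)))
    if (best_idx > 0L) {
      # replay the accepted prefix on the live state
      for (pos in seq_len(best_idx)) {
        v <- move_df$node[[pos]]
        b <- as.integer(move_df$target[[pos]])
        a <- labels[[v]]
        if (a == b) next
        b_key <- as.character(b)
        if (is.na(K_tot[b_key])) K_tot[[b_key]] <- 0
        K_tot[[as.character(a)]] <- K_tot[[as.character(a)]] - k[[v]]
        K_tot[[b_key]] <- K_tot[[b_key]] + k[[v]]
        labels[[v]] <- b
      }
    }
    # greedy phase: strictly improving single-node moves, until exhausted
    gp <- greedy_moves(labels, A, k, m,
                       seed = derive_seed(seed, 500000L + sweep_no), tol = tol)
    labels <- gp$labels
    # merge phase: reunite community pairs whose merger increases Q (the
    # bisective recursion cannot, on its own, undo an early bad cut)
    mg <- merge_communities(labels, A, k, m, tol = tol)
    labels <- mg$labels
    K <- tapply(k, labels, sum)
    K_tot <- stats::setNames(as.numeric(K), names(K))
    sweeps[[sweep_no]] <- list(moves = move_df, best_prefix = best_idx,
                               gain = best, greedy_gain = gp$gain,
                               merges = mg$merges, merge_gain = mg$gain)
    if (best_idx == 0L && gp$gain <= tol && nrow(mg$merges) == 0L) break
  }
  labels <- canonical_labels(labels)
  mem_out <- stats::setNames(labels, network$gene_ids)
  q_after <- modularity_q(network, mem_out)
  part <- structure(list(membership = mem_out, q = q_after,
                         n_communities = length(unique(labels)),
                         seed = seed),
                    class = "network_partition")
  list(partition = part,
       trace = list(sweeps = sweeps, q_before = q_before, q_after = q_after))
}

# Strictly improving single-node moves in seeded random order, applied
# immediately, repeated until a full pass makes no move.
greedy_moves <- function(labels, A, k, m, seed, tol = 1e-10) {
  n <- length(labels)
  gain_total <- 0
  K <- tapply(k, labels, sum)
  K_tot <- stats::setNames(as.numeric(K), names(K))
  pass <- 0L
  repeat {
    pass <- pass + 1L
    order_v <- with_seed(derive_seed(seed, pass), sample.int(n))
    moved <- FALSE
    for (v in order_v) {
      a <- labels[[v]]
      a_key <- as.character(a)
      nbr <- which(A[v, ] == 1L)
      d_v <- table(factor(labels[nbr], levels = names(K_tot)))
      d_v <- stats::setNames(as.numeric(d_v), names(d_v))
      d_va <- d_v[[a_key]]
      cand <- setdiff(names(K_tot)[K_tot > 0], a_key)
      best_dq <- tol
      best_t <- NULL
      for (t in cand) {
        dq <- (d_v[[t]] - d_va) / m -
          k[[v]] * (K_tot[[t]] - K_tot[[a_key]] + k[[v]]) / (2 * m^2)
        if (dq > best_dq) {
          best_dq <- dq
          best_t <- t
        }
      }
      # a new singleton community
      if (sum(labels == a) > 1L) {
        dq_new <- -d_va / m + k[[v]] * (K_tot[[a_key]] - k[[v]]) / (2 * m^2)
        if (dq_new > best_dq) {
          best_dq <- dq_new
          best_t <- "new"
        }
      }
      if (is.null(best_t)) next
      if (best_t == "new") {
        b <- max(labels) + 1L
        K_tot[[as.character(b)]] <- 0
      } else {
        b <- as.integer(best_t)
      }
      K_tot[[a_key]] <- K_tot[[a_key]] - k[[v]]
      K_tot[[as.character(b)]] <- K_tot[[as.character(b)]] + k[[v]]
      labels[[v]] <- b
      gain_total <- gain_total + best_dq
      moved <- TRUE
    }
    if (!moved) break
  }
  list(labels = labels, gain = gain_total)
}

# Greedily merge community pairs while the best merger increases Q.
# Merging c and d changes Q by e_cd / m - K_c K_d / (2 m^2).
merge_communities <- function(labels, A, k, m, tol = 1e-10) {
  merges <- list()
  gain_total <- 0
  repeat {
    labs <- sort(unique(labels))
    if (length(labs) < 2L) break
    S <- vapply(labs, function(l) as.numeric(labels == l), numeric(length(labels)))
    E <- t(S) %*% A %*% S / 2          # E[c,c] = within edges; off-diag half-sums
    E_cd <- (E + t(E))
    diag(E_cd) <- 0                    # e_cd for c != d
    K_c <- as.numeric(t(S) %*% k)
    gain <- E_cd / m - outer(K_c, K_c) / (2 * m^2)
    diag(gain) <- -Inf
    best <- which(gain == max(gain), arr.ind = TRUE)[1L, ]
    if (gain[best[1L], best[2L]] <= tol) break
    from <- labs[max(best)]
    to <- labs[min(best)]
    labels[labels == from] <- to
    gain_total <- gain_total + gain[best[1L], best[2L]]
    merges[[length(merges) + 1L]] <- data.frame(from = from, to = to,
                                                dq = gain[best[1L], best[2L]])
  }
  merges <- if (length(merges)) do.call(rbind, merges) else
    data.frame(from = integer(), to = integer(), dq = numeric())
  list(labels = labels, merges = merges, gain = gain_total)
}

# Relabel community labels to be contiguous from 0 in order of first
# appearance along the node order.
canonical_labels <- function(labels) {
  as.integer(match(labels, unique(labels))) - 1L
}

#' @export
print.network_partition <- function(x, ...) {
  cat(sprintf("network_partition: %d genes in %d communities, Q = %s\n",
              length(x$membership), x$n_communities, format(x$q, digits = 6)))
  invisible(x)
}

#' Exact maximum-modularity partition by exhaustive enumeration
#'
#' Enumerates every set partition (restricted growth strings) of networks
#' with at most 12 nodes and returns the partition with maximal Q. Ties are
#' resolved in favour of the lexicographically smallest canonical labeling.
#' Intended as an exact oracle for testing the heuristic optimizer.
#'
#' @param network A `threshold_network` with at most 12 nodes and at least
#'   one link.
#' @return A `network_partition` with the global maximum Q.
#' @export
brute_force_max_modularity <- function(network) {
  stopifnot(inherits(network, "threshold_network"))
  n <- length(network$gene_ids)
  if (n > 12L) stop_format("brute-force enumeration refused for more than 12 nodes")
  if (network$m < 1) stop_format("modularity is undefined for a network with no links")
  P <- restricted_growth_strings(n)
  A <- network$adjacency
  k <- network$degrees
  m <- network$m
  B <- A - outer(k, k) / (2 * m)
  q_all <- rep(0, nrow(P))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (B[i, j] != 0) q_all <- q_all + B[i, j] * (P[, i] == P[, j])
    }
  }
  q_all <- q_all / (2 * m)
  best <- which(q_all >= max(q_all) - 1e-12)[[1L]]
  mem <- stats::setNames(as.integer(P[best, ]), network$gene_ids)
  structure(list(membership = mem, q = q_all[[best]],
                 n_communities = length(unique(mem)), seed = NA_integer_),
            class = "network_partition")
}

# All set partitions of n items as restricted growth strings, one row per
# partition, in lexicographic order (labels start at 0).
restricted_growth_strings <- function(n) {
  rows <- list()
  rgs <- integer(n)
  recurse <- function(pos, max_lab) {
    if (pos > n) {
      rows[[length(rows) + 1L]] <<- rgs
      return(invisible(NULL))
    }
    for (lab in 0:(max_lab + 1L)) {
      rgs[[pos]] <<- lab
      recurse(pos + 1L, max(max_lab, lab))
    }
  }
  rgs[[1L]] <- 0L
  recurse(2L, 0L)
  if (n == 1L) return(matrix(0L, 1L, 1L))
  do.call(rbind, rows)
}
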