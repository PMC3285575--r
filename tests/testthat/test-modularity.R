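test_that("modularity of toy partitions matches closed forms", {
  net <- bridged_triangles()
  # one community: Q = 0 because modularity-matrix entries sum to zero
  expect_equal(modularity_q(net, stats::setNames(rep(0L, 6), net$gene_ids)), 0)
  split <- stats::setNames(c(0L, 0L, 0L, 1L, 1L, 1L), net$gene_ids)
  expect_equal(modularity_q(net, split), 5 / 14)
  k3 <- complete_graph(3)
  singletons <- stats::setNames(0:2, k3$gene_ids)
  expect_equal(modularity_q(k3, singletons), -1 / 3)
  empty <- threshold_network(matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3])), 1)
  expect_error(modularity_q(empty, singletons), "no links")
  expect_error(modularity_q(net, stats::setNames(0L, "a")), "cover")
})

test_that("modularity matrix rows sum to zero and subgroup form is consistent", {
  for (seed in 1:10) {
    net <- random_graph(12, 0.4, seed)
    B <- modularity_matrix(net)
    expect_true(all(abs(rowSums(B)) < 1e-10))
    g <- 1:5
    Bg <- modularity_matrix(net, g)
    expect_identical(Bg, t(Bg))
    # splitting value: s' Bg s / 4m equals the modularity gain of the split
    s <- c(1, 1, -1, -1, 1)
    rest <- stats::setNames(rep(1L, 12), net$gene_ids)
    rest[g] <- 0L
    merged <- modularity_q(net, rest)
    rest[g[s < 0]] <- 2L
    split_q <- modularity_q(net, rest)
    expect_equal(split_q - merged, as.numeric(t(s) %*% Bg %*% s) / (4 * net$m),
                 tolerance = 1e-12)
  }
})

test_that("brute-force enumeration finds known optima", {
  net <- bridged_triangles()
  bf <- brute_force_max_modularity(net)
  expect_equal(bf$q, 5 / 14)
  expect_equal(bf$n_communities, 2L)
  expect_equal(unname(bf$membership), c(0L, 0L, 0L, 1L, 1L, 1L))

  k4 <- complete_graph(4)
  bf4 <- brute_force_max_modularity(k4)
  expect_equal(bf4$q, 0)
  expect_equal(bf4$n_communities, 1L)

  # 4-cycle: the maximum Q is 0, achieved by the single community (the
  # canonical tie-break picks the lexicographically smallest labeling)
  ids <- letters[1:4]
  A <- matrix(0L, 4, 4, dimnames = list(ids, ids))
  A[1, 2] <- A[2, 3] <- A[3, 4] <- A[4, 1] <- 1L
  A <- A + t(A)
  cyc <- brute_force_max_modularity(as_threshold_network(A))
  expect_equal(cyc$q, 0)
  expect_equal(unname(cyc$membership), rep(0L, 4))

  expect_error(brute_force_max_modularity(random_graph(13, 0.5, 1)), "12 nodes")
})

test_that("leading split divides the bridged triangles and refuses K4", {
  net <- bridged_triangles()
  sp <- leading_split(net, seq_len(6), seed = 1)
  expect_true(sp$divisible)
  groups <- lapply(sp$groups, sort)
  expect_setequal(c(groups[[1]], groups[[2]]), 1:6)
  expect_true(identical(groups[[1]], 1:3) || identical(groups[[1]], 4:6))
  expect_equal(sp$dq, 5 / 14)

  k4 <- complete_graph(4)
  expect_false(leading_split(k4, 1:4, seed = 1)$divisible)
  expect_error(leading_split(net, 1, seed = 1), "at least 2")
})

test_that("partition_network recovers exact optima on toy graphs", {
  net <- bridged_triangles()
  p <- partition_network(net, seed = 5)
  expect_equal(p$q, 5 / 14)
  expect_equal(p$n_communities, 2L)
  expect_equal(modularity_q(net, p), p$q)

  cl <- clique_pair(4)
  pc <- partition_network(cl, seed = 2)
  expect_equal(pc$n_communities, 2L)
  expect_equal(length(unique(pc$membership[1:4])), 1L)
  expect_equal(length(unique(pc$membership[5:8])), 1L)
})

test_that("partitioning is deterministic in the seed and bounded by the oracle", {
  for (seed in 1:30) {
    net <- random_graph(8, withr::with_seed(seed, runif(1, 0.25, 0.7)), seed + 500)
    bf <- brute_force_max_modularity(net)
    p1 <- partition_network(net, seed = seed)
    p2 <- partition_network(net, seed = seed)
    expect_identical(p1$membership, p2$membership)
    expect_lte(p1$q, bf$q + 1e-10)
  }
})

test_that("isolated nodes become their own communities and empty graphs warn", {
  ids <- letters[1:5]
  A <- matrix(0L, 5, 5, dimnames = list(ids, ids))
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- A[1, 3] <- A[3, 1] <- 1L
  net <- as_threshold_network(A)
  p <- partition_network(net, seed = 1)
  expect_equal(length(unique(p$membership[1:3])), 1L)
  expect_false(p$membership[4] == p$membership[5])
  expect_false(p$membership[4] %in% p$membership[1:3])

  empty <- as_threshold_network(matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3])))
  expect_warning(p0 <- partition_network(empty, seed = 1), "no links")
  expect_equal(p0$n_communities, 3L)
})

test_that("final tuning never decreases Q and repairs corrupted optima", {
  net <- bridged_triangles()
  optimum <- stats::setNames(c(0L, 0L, 0L, 1L, 1L, 1L), net$gene_ids)
  ft <- final_tune(net, optimum, seed = 3)
  expect_identical(canonical_sets(ft$partition$membership), canonical_sets(optimum))
  expect_equal(ft$partition$q, 5 / 14)

  corrupted <- optimum
  corrupted[["a"]] <- 1L
  ft2 <- final_tune(net, corrupted, seed = 4)
  expect_equal(ft2$partition$q, 5 / 14)
  expect_identical(canonical_sets(ft2$partition$membership), canonical_sets(optimum))

  # a single community over two disconnected cliques must split
  cl <- clique_pair(4)
  one <- stats::setNames(rep(0L, 8), cl$gene_ids)
  ft3 <- final_tune(cl, one, seed = 5)
  expect_equal(ft3$partition$n_communities, 2L)
  expect_gt(ft3$partition$q, 0)

  # monotonicity on random graph/partition pairs, with trace consistency
  for (i in 1:50) {
    net_i <- random_graph(10, 0.35, 3000 + i)
    mem <- withr::with_seed(4000 + i,
      stats::setNames(sample(0:3, 10, replace = TRUE), net_i$gene_ids))
    mem <- stats::setNames(as.integer(factor(mem)) - 1L, names(mem))
    ft_i <- final_tune(net_i, mem, seed = i)
    expect_gte(ft_i$trace$q_after, ft_i$trace$q_before - 1e-12)
    expect_equal(ft_i$partition$q, modularity_q(net_i, ft_i$partition),
                 tolerance = 1e-10)
  }
})

test_that("incremental move gains agree with full recomputation", {
  net <- random_graph(9, 0.45, 77)
  mem <- withr::with_seed(78, stats::setNames(sample(0:2, 9, replace = TRUE),
                                              net$gene_ids))
  mem <- stats::setNames(as.integer(factor(mem)) - 1L, names(mem))
  ft <- final_tune(net, mem, seed = 79)
  # replay the first sweep move by move against direct Q evaluation
  sweep1 <- ft$trace$sweeps[[1]]
  state <- mem
  q_prev <- modularity_q(net, state)
  for (r in seq_len(nrow(sweep1$moves))) {
    v <- sweep1$moves$node[r]
    state[v] <- as.integer(sweep1$moves$target[r])
    q_now <- modularity_q(net, state)
    expect_equal(q_now - q_prev, sweep1$moves$dq[r], tolerance = 1e-10)
    q_prev <- q_now
  }
})
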