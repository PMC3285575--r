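test_that("ensembles are reproducible and pick up the unique optimum", {
  cl <- clique_pair(4)
  e1 <- run_ensemble(cl, runs = 10, seed = 7)
  e2 <- run_ensemble(cl, runs = 10, seed = 7)
  expect_identical(lapply(e1$partitions, `[[`, "membership"),
                   lapply(e2$partitions, `[[`, "membership"))
  sets <- lapply(e1$partitions, function(p) canonical_sets(p$membership))
  expect_true(all(vapply(sets, identical, logical(1), sets[[1]])))
  expect_length(run_ensemble(cl, runs = 1, seed = 1)$partitions, 1L)
})

test_that("coclassification counts pairwise agreement as proportions", {
  g <- c("a", "b", "c")
  mems <- list(stats::setNames(c(0L, 0L, 1L), g),
               stats::setNames(c(0L, 0L, 0L), g),
               stats::setNames(c(0L, 0L, 1L), g),
               stats::setNames(c(0L, 1L, 1L), g))
  C <- coclassification(mems)
  expect_equal(C$R, 4L)
  expect_equal(C$C["a", "b"], 0.75)
  expect_equal(C$C["a", "c"], 0.25)
  expect_equal(C$C["b", "c"], 0.5)
  expect_identical(C$C, t(C$C))
  expect_true(all(diag(C$C) == 1))
  expect_true(all(abs(C$C * C$R - round(C$C * C$R)) < 1e-12))

  same <- coclassification(mems[c(1, 1, 1)])
  expect_true(all(same$C %in% c(0, 1)))
})

test_that("core communities at tau = 1 are exact equivalence classes", {
  ids <- paste0("g", 1:6)
  C <- matrix(0, 6, 6, dimnames = list(ids, ids))
  C[1:3, 1:3] <- 1
  C[4:6, 4:6] <- 1
  diag(C) <- 1
  cores <- core_communities(make_coclass(C, 10L))
  expect_length(cores$sets, 2L)
  expect_equal(unname(cores$sizes), c(3L, 3L))
  expect_setequal(cores$sets[[1]], c("g1", "g2", "g3"))

  # ties in size break on the lexicographically smallest member
  expect_true(cores$sets[[1]][1] < cores$sets[[2]][1])

  # all off-diagonal below 1: all singleton cores
  C2 <- diag(6)
  dimnames(C2) <- list(ids, ids)
  singles <- core_communities(make_coclass(C2, 10L))
  expect_length(singles$sets, 6L)

  # cores partition the universe for random ensembles
  for (seed in 1:5) {
    net <- random_graph(12, 0.35, 6000 + seed)
    ens <- run_ensemble(net, runs = 5, seed = seed)
    cc <- core_communities(coclassification(ens))
    expect_setequal(unlist(cc$sets), net$gene_ids)
    expect_equal(sum(cc$sizes), 12L)
    # every within-core pair agrees in every partitioning
    for (s in cc$sets) {
      if (length(s) >= 2) {
        expect_true(all(coclassification(ens)$C[s, s] == 1))
      }
    }
  }
})

test_that("cores below tau = 1 are connected components of the tau graph", {
  ids <- paste0("g", 1:4)
  C <- diag(4)
  dimnames(C) <- list(ids, ids)
  C["g1", "g2"] <- C["g2", "g1"] <- 0.8
  C["g2", "g3"] <- C["g3", "g2"] <- 0.8
  cores <- core_communities(make_coclass(C, 10L), tau = 0.7)
  expect_length(cores$sets, 2L)
  expect_setequal(cores$sets[[1]], c("g1", "g2", "g3"))
})

test_that("hierarchy fraction counts preserved co-core pairs", {
  coarse <- make_cores(list(c("a", "b", "c", "d"), c("e", "f")))
  fine_nested <- make_cores(list(c("a", "b"), c("c", "d"), c("e", "f")))
  expect_equal(hierarchy_fraction(fine_nested, coarse), 1)
  expect_equal(hierarchy_fraction(coarse, coarse), 1)

  # a fine 4-core drawing two genes from each of two coarse cores:
  # preserved pairs = C(2,2) + C(2,2) = 2 of C(4,2) = 6
  coarse2 <- make_cores(list(c("a", "b"), c("c", "d")))
  fine2 <- make_cores(list(c("a", "b", "c", "d")))
  expect_equal(hierarchy_fraction(fine2, coarse2), 2 / 6)

  all_single <- make_cores(as.list(c("a", "b", "c", "d")))
  expect_warning(res <- hierarchy_fraction(all_single, coarse2), "undefined")
  expect_true(is.na(res))
  expect_error(hierarchy_fraction(fine2, make_cores(list(c("x", "y")))), "universe")
})

test_that("hierarchy graph weights are daughter-gene proportions summing to one", {
  coarse <- make_cores(list(c("a", "b", "c", "d"), c("e", "f")))
  fine <- make_cores(list(c("a", "b", "c", "e"), c("d", "f")))
  hg <- hierarchy_graph(list(`1` = coarse, `2` = fine))
  expect_equal(nrow(hg$nodes), 4L)
  d1 <- hg$edges[hg$edges$daughter_core == 1, ]
  expect_setequal(round(d1$weight, 10), c(0.75, 0.25))
  for (d in unique(hg$edges$daughter_core)) {
    expect_equal(sum(hg$edges$weight[hg$edges$daughter_core == d]), 1,
                 tolerance = 1e-12)
  }
  # perfectly nested levels: single parent with weight 1 each
  nested <- hierarchy_graph(list(`1` = coarse,
                                 `2` = make_cores(list(c("a", "b"), c("c", "d"), c("e", "f")))))
  expect_true(all(nested$edges$weight == 1))
  # single level: nodes but no edges
  solo <- hierarchy_graph(list(`1` = coarse))
  expect_equal(nrow(solo$edges), 0L)
  expect_equal(nrow(solo$nodes), 2L)
})

test_that("display order lists cores recursively by decreasing size", {
  lvl1 <- make_cores(list(c("p", "q", "r", "s", "t"), c("x", "y", "z"), c("m", "n")))
  ord <- display_order(list(lvl1))
  expect_equal(ord[1:5], c("p", "q", "r", "s", "t"))
  expect_equal(ord[6:8], c("x", "y", "z"))

  # nested two-level toy: within the big core, the larger subcore first
  lvl2 <- make_cores(list(c("r", "s", "t"), c("p", "q"), c("x", "y", "z"), c("m", "n")))
  ord2 <- display_order(list(lvl1, lvl2))
  expect_equal(ord2[1:3], c("r", "s", "t"))
  expect_equal(ord2[4:5], c("p", "q"))

  # equal sizes: lexicographically smallest member first
  tie <- make_cores(list(c("b", "d"), c("a", "c")))
  expect_equal(display_order(list(tie)), c("a", "c", "b", "d"))
})

test_that("composite image encodes the three thresholds in RGB channels", {
  ids <- c("a", "b")
  ones <- matrix(1, 2, 2, dimnames = list(ids, ids))
  eye <- diag(2)
  dimnames(eye) <- list(ids, ids)
  img_white <- composite_matrix_image(make_coclass(ones, 10L),
                                      make_coclass(ones, 10L),
                                      make_coclass(ones, 10L))
  expect_true(all(img_white == 1))
  img_black <- composite_matrix_image(make_coclass(eye, 10L),
                                      make_coclass(eye, 10L),
                                      make_coclass(eye, 10L))
  expect_true(all(img_black[1, 2, ] == 0))
  # only the lowest threshold co-classifies: pure blue off-diagonal
  img_blue <- composite_matrix_image(make_coclass(ones, 10L),
                                     make_coclass(eye, 10L),
                                     make_coclass(eye, 10L))
  expect_equal(unname(img_blue[1, 2, ]), c(0, 0, 1))
  bad <- make_coclass(matrix(1, 2, 2, dimnames = list(c("q", "r"), c("q", "r"))), 10L)
  expect_error(composite_matrix_image(bad, make_coclass(eye, 10L),
                                      make_coclass(eye, 10L)), "universe")
})
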