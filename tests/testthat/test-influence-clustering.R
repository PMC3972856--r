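test_that("centralization matches its boundary and hand-derived cases", {
  expect_equal(centralization(c(1, 0, 0, 0)), 1)       # one-hot profile
  expect_equal(centralization(c(0.3, 0.3, 0.3)), 0)    # uniform: no core
  expect_equal(centralization(c(0.6, 0.4, 0.2)), 0.75)
  expect_equal(centralization(5), 0)                   # single member
  expect_error(centralization(numeric(0)), "empty")
  # range invariant on random profiles
  set.seed(8)
  for (k in 1:25) {
    v <- runif(sample(2:9, 1))
    cg <- centralization(v)
    expect_gte(cg, 0)
    expect_lte(cg, 1)
  }
})

test_that("total centralization sums per-cluster values over the partition", {
  ca <- c(a = 0.6, b = 0.4, c = 0.2, d = 0.5, e = 0.5)
  memb <- c(a = 1L, b = 1L, c = 1L, d = 2L, e = 2L)
  expect_equal(total_centralization(memb, ca), 0.75)   # 0.75 + 0
  # two one-hot clusters
  ca2 <- c(a = 1, b = 0, c = 0, d = 1, e = 0, f = 0)
  memb2 <- c(a = 1L, b = 1L, c = 1L, d = 2L, e = 2L, f = 2L)
  expect_equal(total_centralization(memb2, ca2), 2)
  # uniform clusters -> 0
  expect_equal(total_centralization(memb2, stats::setNames(rep(0.3, 6),
                                                           names(ca2))), 0)
})

test_that("contested nodes join the cluster maximizing total centralization", {
  # x (C_A 0) adjacent to cluster A = {a1: 0.8, a2: 0} and B = {b1, b2, b3:
  # all 0.8}. Joining B raises B from 0 to 1/3 while A keeps 1; joining A
  # leaves the total at 1. The optimizer must pick B.
  g <- named_graph(rbind(c("x", "a2"), c("x", "b3"), c("a1", "a2"),
                         c("b1", "b2"), c("b2", "b3"), c("b1", "b3")))
  memb <- c(a1 = 1L, a2 = 1L, b1 = 2L, b2 = 2L, b3 = 2L, x = NA_integer_)
  ca <- c(a1 = 0.8, a2 = 0, b1 = 0.8, b2 = 0.8, b3 = 0.8, x = 0)
  expect_equal(assign_contested("x", memb, g, ca), 2L)

  # single candidate cluster
  memb1 <- c(a1 = 3L, a2 = 3L, b1 = NA_integer_, b2 = NA_integer_,
             b3 = NA_integer_, x = NA_integer_)
  expect_equal(assign_contested("x", memb1, g, ca), 3L)

  # equal objective: tie broken by more edges into the cluster
  g2 <- named_graph(rbind(c("x", "a1"), c("x", "a2"), c("x", "b1"),
                          c("a1", "a2"), c("b1", "b2")))
  memb2 <- c(a1 = 1L, a2 = 1L, b1 = 2L, b2 = 2L, x = NA_integer_)
  ca0 <- stats::setNames(rep(0, 5), names(memb2))
  ca0["x"] <- 0
  expect_equal(assign_contested("x", memb2, g2, ca0), 1L)

  # no clustered neighbour: defer
  memb3 <- c(a1 = NA_integer_, a2 = NA_integer_, b1 = 1L, b2 = 1L,
             b3 = 1L, x = NA_integer_)
  g3 <- named_graph(rbind(c("x", "a1"), c("a2", "a1"), c("b1", "b2"),
                          c("b2", "b3"), c("b1", "b3")))
  expect_true(is.na(assign_contested("x", memb3, g3, ca)))
})

test_that("complete and edgeless graphs yield the expected partitions", {
  f <- influence_cluster(igraph::make_full_graph(5))
  expect_equal(f$n_clusters, 1)
  expect_length(f$membership, 5)

  f0 <- influence_cluster(igraph::make_empty_graph(4, directed = FALSE))
  expect_equal(f0$n_clusters, 4)
  expect_equal(sort(unname(f0$membership)), 1:4)
})

test_that("the fitted partition is complete, deterministic, and state-conserving", {
  pp <- planted_partition(4, 25, 0.3, 0.02, seed = 3)
  fit <- influence_cluster(pp$graph)
  n <- igraph::vcount(pp$graph)
  # completeness: every node assigned exactly once
  expect_setequal(names(fit$membership), igraph::V(pp$graph)$name)
  expect_false(anyNA(fit$membership))
  expect_equal(sum(fit$sizes), n)
  # P/Q/R conservation after every recorded event
  expect_true(all(fit$trace$P + fit$trace$Q + fit$trace$R == n))
  # founding cap
  expect_lte(fit$founding_events, ceiling(0.2 * n))
  # determinism
  fit2 <- influence_cluster(pp$graph)
  expect_identical(fit2$membership, fit$membership)
  # every reported core belongs to the cluster it heads
  expect_true(all(fit$membership[unname(fit$cores)] ==
                    as.integer(names(fit$cores))))
})

test_that("disconnected graphs are covered via singleton founding", {
  g <- igraph::disjoint_union(igraph::make_full_graph(4),
                              igraph::make_full_graph(4))
  igraph::V(g)$name <- letters[1:8]
  fit <- influence_cluster(g)
  expect_false(anyNA(fit$membership))
  expect_gte(fit$n_clusters, 2)
  # the two cliques never share a cluster
  expect_length(intersect(unique(fit$membership[letters[1:4]]),
                          unique(fit$membership[letters[5:8]])), 0)
})

test_that("planted blocks are recovered in the easy regime", {
  pp <- planted_partition(4, 25, 0.3, 0.02, seed = 1)
  fit <- influence_cluster(pp$graph)
  expect_gte(nmi(fit$membership, pp$truth), 0.8)
})
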