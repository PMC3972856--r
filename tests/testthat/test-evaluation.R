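test_that("cluster scores evaluate the conductance and expansion formulas", {
  # one triangle of the bridged graph: 3 internal edges, 1 boundary edge
  s <- score_cluster(bridged_triangles(), c("a", "b", "c"))
  expect_equal(s$n_S, 3)
  expect_equal(s$m_S, 3)
  expect_equal(s$c_S, 1)
  expect_equal(s$conductance, 1 / 7)
  expect_equal(s$expansion, 1 / 3)

  # whole graph: no boundary
  g <- two_triangles()
  sw <- score_cluster(g, igraph::V(g)$name)
  expect_equal(sw$conductance, 0)
  expect_equal(sw$expansion, 0)

  # isolated vertex has no incident edges: conductance defined 0
  gi <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(gi)$name <- "z"
  expect_equal(score_cluster(gi, "z")$conductance, 0)

  expect_error(score_cluster(g, character(0)), "empty")
  expect_error(score_cluster(g, "nope"), "unknown")
})

test_that("every edge end is accounted once: sum(2 m_S + c_S) = 2m", {
  for (seed in 1:5) {
    g <- random_named_gnp(25, 0.15, seed)
    memb <- stats::setNames(sample(1:4, 25, replace = TRUE),
                            igraph::V(g)$name)
    sc <- score_partition(g, memb)
    expect_equal(sum(2 * sc$m_S + sc$c_S), 2 * igraph::ecount(g))
    expect_true(all(sc$conductance >= 0 & sc$conductance <= 1))
    expect_true(all(sc$expansion >= 0))
  }
})

test_that("boundary edges are symmetric between a cluster and its complement", {
  g <- random_named_gnp(20, 0.2, 9)
  members <- igraph::V(g)$name[1:7]
  rest <- setdiff(igraph::V(g)$name, members)
  expect_equal(score_cluster(g, members)$c_S, score_cluster(g, rest)$c_S)
})

test_that("NCP profiles report per-size minima and are relabel-invariant", {
  g <- two_triangles()
  memb <- c(a = 1L, b = 1L, c = 1L, d = 2L, e = 2L, f = 2L)
  prof <- ncp_profile(g, memb)
  expect_equal(prof$profile$size, 3)
  expect_equal(prof$profile$best_conductance, 0)
  expect_equal(prof$profile$best_expansion, 0)
  expect_equal(prof$mean_conductance, 0)

  gb <- bridged_triangles()
  profb <- ncp_profile(gb, memb)
  expect_equal(profb$profile$best_conductance, 1 / 7)
  expect_equal(profb$profile$best_expansion, 1 / 3)

  memb2 <- c(a = 9L, b = 9L, c = 9L, d = 4L, e = 4L, f = 4L)
  expect_equal(ncp_profile(gb, memb2)$profile, profb$profile)

  expect_error(ncp_profile(gb, c(a = 1L)), "integrity")
})

test_that("algorithm comparison counts strict wins over common sizes", {
  mk <- function(sizes, cond, exp) {
    data.frame(cluster = seq_along(sizes), n_S = sizes,
               m_S = 1, c_S = 1, conductance = cond, expansion = exp)
  }
  a <- mk(c(3, 4, 5, 6), c(0.1, 0.2, 0.3, 0.4), c(1, 1, 1, 1))
  expect_equal(compare_partitions(a, a)$win_fraction_conductance, 0)

  b <- mk(c(3, 4, 5, 6), c(0.2, 0.3, 0.4, 0.5), c(1, 1, 1, 1))
  cmp <- compare_partitions(a, b)
  expect_equal(cmp$win_fraction_conductance, 1)
  expect_equal(cmp$win_fraction_expansion, 0)

  # A better at 3 of 4 common sizes
  c3 <- mk(c(3, 4, 5, 6), c(0.05, 0.1, 0.2, 0.55), c(1, 1, 1, 1))
  expect_equal(compare_partitions(c3, b)$win_fraction_conductance, 0.75)

  # sizes present in only one profile are listed, not counted
  d <- mk(c(3, 9), c(0.2, 0.1), c(1, 1))
  cmpd <- compare_partitions(a, d)
  expect_equal(cmpd$common$size, 3)
  expect_equal(cmpd$only_a, c(4, 5, 6))
  expect_equal(cmpd$only_b, 9)

  # no common sizes: win fraction undefined
  e <- mk(7, 0.5, 1)
  expect_true(is.na(compare_partitions(a, e)$win_fraction_conductance))
})
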