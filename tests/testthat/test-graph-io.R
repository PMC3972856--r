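test_that("edge lists parse with comments, dedup, and self-loop handling", {
  f <- withr::local_tempfile()
  writeLines(c("# header", "% other comment", "", "a b", "b c extra-token",
               "b a", "a b"), f)
  g <- read_edge_list(f)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_true(igraph::are_adjacent(g, "a", "b"))
  expect_true(igraph::are_adjacent(g, "b", "c"))
  expect_false(igraph::are_adjacent(g, "a", "c"))

  f2 <- withr::local_tempfile()
  writeLines(c("a a", "a b"), f2)
  expect_message(g2 <- read_edge_list(f2), "1 self-loop")
  expect_equal(igraph::vcount(g2), 2)
  expect_equal(igraph::ecount(g2), 1)

  f3 <- withr::local_tempfile()
  writeLines(c("a b", "lonely"), f3)
  expect_error(read_edge_list(f3), "line 2")

  f4 <- withr::local_tempfile()
  writeLines(c("# only a comment"), f4)
  expect_equal(igraph::vcount(read_edge_list(f4)), 0)
})

test_that("GML graphs are symmetrized and labelled, bad references error", {
  f <- withr::local_tempfile()
  writeLines(gml_lines(directed = TRUE, nodes = 0:2,
                       edges = rbind(c(0, 1), c(1, 2), c(2, 0))), f)
  g <- read_gml(f)
  expect_false(igraph::is_directed(g))
  expect_equal(igraph::ecount(g), 3)
  expect_setequal(igraph::V(g)$name, c("0", "1", "2"))

  f2 <- withr::local_tempfile()
  writeLines(gml_lines(directed = FALSE, nodes = 0:1,
                       edges = rbind(c(0, 1)), labels = c("A", "B")), f2)
  g2 <- read_gml(f2)
  expect_setequal(igraph::V(g2)$name, c("A", "B"))
  expect_true(igraph::are_adjacent(g2, "A", "B"))

  f3 <- withr::local_tempfile()
  writeLines(gml_lines(directed = FALSE, nodes = 0:1,
                       edges = rbind(c(0, 99))), f3)
  expect_error(read_gml(f3), "format error")
})

test_that("partition files round-trip and enforce integrity", {
  memb <- c(a = 1L, b = 1L, c = 2L)
  f <- withr::local_tempfile()
  write_partition(memb, f)
  expect_identical(read_partition(f), memb)

  # non-contiguous ids accepted
  write_partition(c(a = 7L, b = 7L), f)
  expect_identical(unname(read_partition(f)), c(7L, 7L))

  # unassigned graph node is an integrity error
  g <- path_abc()
  expect_error(write_partition(c(a = 1L, b = 1L), f, graph = g),
               "integrity error")

  # duplicate node rows are an integrity error
  writeLines(c("node\tcluster", "a\t1", "a\t2"), f)
  expect_error(read_partition(f), "integrity error")
})

test_that("graph_summary reports the six descriptive statistics", {
  s <- graph_summary(triangle())
  expect_equal(s$n_nodes, 3)
  expect_equal(s$n_edges, 3)
  expect_equal(s$n_triangles, 1)
  expect_equal(s$avg_clustering, 1)
  expect_equal(s$diameter, 1)
  expect_equal(s$avg_shortest_path, 1)

  s2 <- graph_summary(path_abc())
  expect_equal(s2$n_triangles, 0)
  expect_equal(s2$avg_clustering, 0)  # degree-1 nodes contribute 0
  expect_equal(s2$diameter, 2)
  expect_equal(s2$avg_shortest_path, 4 / 3)

  expect_error(graph_summary(igraph::make_empty_graph(0)), "empty")
})

test_that("edge handshake and triangle consistency hold on random graphs", {
  for (seed in 1:5) {
    g <- random_named_gnp(30, 0.15, seed)
    s <- graph_summary(g)
    expect_equal(2 * s$n_edges, sum(igraph::degree(g)))
    # triangles via per-node neighbour-edge counts: sum(E_x) = 3 * triangles
    ex <- node_metrics(g)$table$neighbor_edges
    expect_equal(sum(ex) / 3, s$n_triangles)
  }
})

test_that("path statistics are restricted to the largest component", {
  # triangle plus an isolated edge: diameter/asp from the triangle
  g <- named_graph(rbind(c("a", "b"), c("b", "c"), c("a", "c"), c("x", "y")))
  s <- graph_summary(g)
  expect_equal(s$diameter, 1)
  expect_equal(s$avg_shortest_path, 1)
  expect_equal(s$n_nodes, 5)
})
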