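# Fixture graphs and independent oracles shared across the suite.

named_graph <- function(edges) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  labels <- sort(igraph::V(g)$name)
  igraph::permute(g, match(igraph::V(g)$name, labels))
}

path_abc <- function() named_graph(rbind(c("a", "b"), c("b", "c")))

star4 <- function() {
  named_graph(rbind(c("h", "a"), c("h", "b"), c("h", "c"), c("h", "d")))
}

triangle <- function() {
  named_graph(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
}

cycle4 <- function() {
  named_graph(rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a")))
}

two_triangles <- function() {
  named_graph(rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                    c("d", "e"), c("e", "f"), c("d", "f")))
}

# two triangles joined by a single bridge edge c--d (m = 7)
bridged_triangles <- function() {
  named_graph(rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                    c("d", "e"), c("e", "f"), c("d", "f"), c("c", "d")))
}

random_named_gnp <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# Oracle: betweenness by explicit all-pairs geodesic enumeration. Path counts
# come from per-source BFS layering (sigma DP), independent of the
# implementation under test.
oracle_betweenness <- function(g) {
  n <- igraph::vcount(g)
  labels <- igraph::V(g)$name
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    sg <- rep(0, n); sg[s] <- 1
    frontier <- s
    while (length(frontier) > 0L) {
      nxt <- integer(0)
      for (u in frontier) for (v in adj[[u]]) {
        if (is.infinite(d[v])) { d[v] <- d[u] + 1; nxt <- c(nxt, v) }
      }
      nxt <- unique(nxt)
      for (v in nxt) sg[v] <- sum(sg[adj[[v]][d[adj[[v]]] == d[v] - 1]])
      frontier <- nxt
    }
    dist[s, ] <- d
    sigma[s, ] <- sg
  }
  cb <- rep(0, n)
  for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
    if (is.infinite(dist[s, t])) next
    for (x in seq_len(n)) {
      if (x == s || x == t) next
      if (dist[s, x] + dist[x, t] == dist[s, t]) {
        cb[x] <- cb[x] + sigma[s, x] * sigma[x, t] / sigma[s, t]
      }
    }
  }
  stats::setNames(cb * 2 / ((n - 1) * (n - 2)), labels)
}

# Oracle: maximum modularity reachable by ANY sequence of merges of
# edge-connected communities, by breadth-first enumeration of partition
# states (feasible for n <= 8).
oracle_fn_max_q <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  key <- function(p) paste(match(p, unique(p)), collapse = ",")
  seen <- new.env(hash = TRUE)
  start <- seq_len(n)
  qmax <- igraph::modularity(g, start)
  stack <- list(start)
  assign(key(start), TRUE, envir = seen)
  while (length(stack) > 0L) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    cp <- unique(t(apply(cbind(p[el[, 1]], p[el[, 2]]), 1, sort)))
    cp <- cp[cp[, 1] != cp[, 2], , drop = FALSE]
    if (nrow(cp) == 0L) next
    for (r in seq_len(nrow(cp))) {
      p2 <- p
      p2[p2 == cp[r, 2]] <- cp[r, 1]
      k2 <- key(p2)
      if (!exists(k2, envir = seen)) {
        assign(k2, TRUE, envir = seen)
        q2 <- igraph::modularity(g, p2)
        if (q2 > qmax) qmax <- q2
        stack[[length(stack) + 1L]] <- p2
      }
    }
  }
  qmax
}

# Replay a fast_newman merge history and return the membership after k merges.
replay_merges <- function(fit, k) {
  memb <- seq_along(fit$membership)
  if (k > 0L) for (r in seq_len(k)) {
    memb[memb == fit$merge_history[r, "from"]] <- fit$merge_history[r, "into"]
  }
  stats::setNames(memb, names(fit$membership))
}

gml_lines <- function(directed, nodes, edges, labels = NULL) {
  out <- c("graph [", if (directed) "  directed 1")
  for (i in seq_along(nodes)) {
    out <- c(out, "  node [", paste0("    id ", nodes[i]),
             if (!is.null(labels)) paste0("    label \"", labels[i], "\""),
             "  ]")
  }
  for (r in seq_len(nrow(edges))) {
    out <- c(out, "  edge [", paste0("    source ", edges[r, 1]),
             paste0("    target ", edges[r, 2]), "  ]")
  }
  c(out, "]")
}
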