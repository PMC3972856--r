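#' Normalized betweenness centrality
#'
#' For each node x, the fraction of all-pairs geodesics (unweighted shortest
#' paths) that pass through x as an interior node, normalized by the maximum
#' possible count (n - 1)(n - 2) / 2, so values lie in \[0, 1\]. Pairs in
#' different components contribute nothing. Graphs with fewer than three nodes
#' have all values defined as 0.
#'
#' @param g An undirected igraph graph with named vertices.
#' @return Named numeric vector of C_B values, one per node.
#' @export
betweenness_centrality <- function(g) {
  if (igraph::vcount(g) == 0L) stop("betweenness_centrality: empty graph")
  nm <- igraph::V(g)$name
  if (igraph::vcount(g) < 3L) {
    return(stats::setNames(rep(0, igraph::vcount(g)), nm))
  }
  stats::setNames(igraph::betweenness(g, directed = FALSE, normalized = TRUE),
                  nm)
}

#' Local clustering quantities of one node
#'
#' Degree k_x, the number of edges E_x among the node's neighbours, and the
#' local clustering coefficient c_x = 2 E_x / (k_x (k_x - 1)), defined as 0
#' for degree below 2.
#'
#' @param g An undirected igraph graph with named vertices.
#' @param x A node label.
#' @return Named list with `degree`, `neighbor_edges`, `local_clustering`.
#' @examples
#' g <- igraph::make_full_graph(3)
#' igraph::V(g)$name <- c("a", "b", "c")
#' local_clustering(g, "a") # k = 2, E = 1, c = 1
#' @export
local_clustering <- function(g, x) {
  if (!(x %in% igraph::V(g)$name)) stop("unknown node: ", x)
  k <- as.integer(igraph::degree(g, x))
  ex <- as.integer(igraph::count_triangles(g, x))
  list(degree = k, neighbor_edges = ex,
       local_clustering = if (k >= 2L) 2 * ex / (k * (k - 1)) else 0)
}

#' Core influence of every node
#'
#' The core-influence score C_A(x) = C_B(x) / c~_x divides a node's normalized
#' betweenness centrality by its local clustering coefficient, so that brokers
#' whose neighbourhoods are sparsely interconnected are amplified. To keep the
#' score finite when a neighbourhood has no internal edges, E_x is floored at 1
#' inside the denominator: c~_x = 2 max(E_x, 1) / (k_x (k_x - 1)) for k_x >= 2.
#' Nodes of degree < 2 have C_A = 0.
#'
#' @param g An undirected igraph graph with named vertices.
#' @return Named numeric vector of C_A values.
#' @seealso [node_metrics()] for all per-node quantities at once.
#' @export
core_influence <- function(g) {
  node_metrics(g)$core_influence_vec
}

#' All per-node metrics
#'
#' Computes, for every node: degree, neighbour-edge count E_x, local
#' clustering coefficient c_x, normalized betweenness centrality C_B, and the
#' core-influence score C_A (see [core_influence()] for the flooring
#' convention).
#'
#' @param g An undirected igraph graph with named vertices.
#' @return A list of class `node_metrics` with a data frame `table` (columns
#'   `node`, `degree`, `neighbor_edges`, `local_clustering`, `betweenness`,
#'   `core_influence`) and named vectors `betweenness_vec`,
#'   `core_influence_vec`, `degree_vec`.
#' @export
node_metrics <- function(g) {
  if (igraph::vcount(g) == 0L) stop("node_metrics: empty graph")
  nm <- igraph::V(g)$name
  if (is.null(nm)) stop("node_metrics: graph vertices must be named")
  k <- as.integer(igraph::degree(g))
  ex <- as.integer(igraph::count_triangles(g))
  cx <- ifelse(k >= 2L, 2 * ex / (k * (k - 1)), 0)
  cb <- as.numeric(betweenness_centrality(g))
  ctilde <- ifelse(k >= 2L, 2 * pmax(ex, 1L) / (k * (k - 1)), NA_real_)
  ca <- ifelse(k >= 2L, cb / ctilde, 0)
  tab <- data.frame(node = nm, degree = k, neighbor_edges = ex,
                    local_clustering = cx, betweenness = cb,
                    core_influence = ca, stringsAsFactors = FALSE)
  out <- list(table = tab,
              betweenness_vec = stats::setNames(cb, nm),
              core_influence_vec = stats::setNames(ca, nm),
              degree_vec = stats::setNames(k, nm))
  class(out) <- "node_metrics"
  out
}

#' @export
print.node_metrics <- function(x, n = 10L, ...) {
  cat("Per-node metrics (", nrow(x$table), " nodes)\n", sep = "")
  ord <- order(-x$table$core_influence, -x$table$degree, x$table$node)
  print(utils::head(x$table[ord, ], n), row.names = FALSE)
  if (nrow(x$table) > n) cat("  ... top", n, "by core influence shown\n")
  invisible(x)
}
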