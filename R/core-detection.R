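#' Parameters for core detection and clustering
#'
#' The K-function acceptance interval and the candidate-core fraction. The
#' defaults — interval \[1.96, 2.71\] and the Pareto fraction 0.20 — are the
#' constants the method was published with.
#'
#' @param k_low Lower bound of the K acceptance interval (closed). Default 1.96.
#' @param k_high Upper bound of the K acceptance interval (closed). Default 2.71.
#' @param core_fraction Fraction of nodes eligible as candidate cores, taken
#'   from the top of the core-influence ordering. Default 0.20.
#' @return A list of class `core_params`.
#' @export
core_params <- function(k_low = 1.96, k_high = 2.71, core_fraction = 0.20) {
  if (!(k_low > 0 && k_low <= k_high)) {
    stop("core_params: need 0 < k_low <= k_high")
  }
  if (!(core_fraction > 0 && core_fraction <= 1)) {
    stop("core_params: need 0 < core_fraction <= 1")
  }
  structure(list(k_low = k_low, k_high = k_high,
                 core_fraction = core_fraction), class = "core_params")
}

#' Evaluate the K function for a node against its current cluster
#'
#' K(i) compares the actual number of edges m_i between node i and the other
#' members of its cluster with the expectation under random wiring:
#' K(i) = m_i / \[(d_i / d) ((d_q - d_i) / (d - d_i)) m\], where d_i is the
#' node's degree, d_q the degree sum of its cluster (including the node), d
#' the degree sum of the whole graph and m the total edge count. When the
#' whole connected graph is a single cluster, K(i) = 2 for every node.
#' Degenerate states (d_i = d, or a singleton cluster with d_q = d_i) are
#' defined as K = 0.
#'
#' @param g An undirected igraph graph with named vertices.
#' @param membership Named integer vector (or [core_partition]) assigning every
#'   relevant node to a cluster; `node` must be assigned.
#' @param node A node label.
#' @return A list of class `k_evaluation` with fields `node`, `m_i`, `d_i`,
#'   `d_q`, `d`, `m`, `k_value`.
#' @export
k_function <- function(g, membership, node) {
  memb <- as_membership(membership)
  if (!(node %in% names(memb)) || is.na(memb[[node]])) {
    stop("k_function: node ", node, " is not assigned to a cluster")
  }
  deg <- igraph::degree(g)
  m <- igraph::ecount(g)
  d <- 2 * m
  d_i <- as.integer(deg[[node]])
  members <- names(memb)[memb == memb[[node]]]
  d_q <- sum(deg[members])
  nbrs <- igraph::V(g)$name[igraph::neighbors(g, node)]
  m_i <- sum(nbrs %in% setdiff(members, node))
  k_value <- if (d_i == 0L || d_i == d || d_q == d_i) {
    0
  } else {
    m_i / ((d_i / d) * ((d_q - d_i) / (d - d_i)) * m)
  }
  structure(list(node = node, m_i = m_i, d_i = d_i, d_q = d_q,
                 d = d, m = m, k_value = k_value),
            class = "k_evaluation")
}

#' Is a node eligible to found an independent cluster?
#'
#' True when its K value falls inside the closed acceptance interval
#' \[k_low, k_high\].
#'
#' @param k A `k_evaluation` (from [k_function()]) or a bare numeric K value.
#' @param params A [core_params()] list.
#' @return Logical flag.
#' @export
is_core_eligible <- function(k, params = core_params()) {
  kv <- if (inherits(k, "k_evaluation")) k$k_value else as.numeric(k)
  kv >= params$k_low & kv <= params$k_high
}

#' Candidate core nodes
#'
#' The top ceil(core_fraction * n) nodes under the configured ordering.
#' The canonical key is core influence descending, with ties broken by degree
#' descending then label ascending; betweenness or degree can be used as the
#' primary key instead.
#'
#' @param metrics A [node_metrics()] object.
#' @param params A [core_params()] list.
#' @param order_by Primary ordering key: `"core_influence"` (default),
#'   `"betweenness"` or `"degree"`.
#' @return Character vector of candidate labels, highest-ranked first.
#' @export
candidate_cores <- function(metrics, params = core_params(),
                            order_by = c("core_influence", "betweenness",
                                         "degree")) {
  order_by <- match.arg(order_by)
  tab <- metrics$table
  key <- switch(order_by,
                core_influence = tab$core_influence,
                betweenness = tab$betweenness,
                degree = tab$degree)
  ord <- order(-key, -tab$degree, tab$node)
  n_cand <- as.integer(ceiling(params$core_fraction * nrow(tab)))
  tab$node[ord][seq_len(n_cand)]
}
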