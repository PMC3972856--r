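#' Conductance and expansion of one cluster
#'
#' For a node set S: m_S internal edges (both endpoints in S), c_S boundary
#' edges (exactly one endpoint in S). Conductance = c_S / (2 m_S + c_S)
#' (defined 0 when S has no incident edges at all) and expansion = c_S / n_S.
#' Lower is better for both.
#'
#' @param g An undirected igraph graph with named vertices.
#' @param members Character vector of node labels, nonempty, subset of the
#'   graph's nodes.
#' @return List with `n_S`, `m_S`, `c_S`, `conductance`, `expansion`.
#' @examples
#' g <- igraph::make_full_graph(4)
#' igraph::V(g)$name <- letters[1:4]
#' score_cluster(g, c("a", "b"))
#' @export
score_cluster <- function(g, members) {
  if (length(members) == 0L) stop("score_cluster: empty member set")
  nm <- igraph::V(g)$name
  if (!all(members %in% nm)) {
    stop("score_cluster: unknown node(s): ",
         paste(setdiff(members, nm), collapse = ", "))
  }
  el <- igraph::as_edgelist(g)
  in_s <- matrix(el %in% members, ncol = 2L)
  ends_in <- rowSums(in_s)
  m_s <- sum(ends_in == 2L)
  c_s <- sum(ends_in == 1L)
  list(n_S = length(members), m_S = m_s, c_S = c_s,
       conductance = if (2 * m_s + c_s == 0L) 0 else c_s / (2 * m_s + c_s),
       expansion = c_s / length(members))
}

#' Score every cluster of a partition
#'
#' @param g An undirected igraph graph with named vertices.
#' @param membership Named integer vector (or [core_partition]) covering all
#'   nodes.
#' @return Data frame with one row per cluster: `cluster`, `n_S`, `m_S`,
#'   `c_S`, `conductance`, `expansion`.
#' @export
score_partition <- function(g, membership) {
  memb <- as_membership(membership)
  nm <- igraph::V(g)$name
  missing <- setdiff(nm, names(memb))
  if (length(missing) > 0L) {
    stop("score_partition: integrity error, unassigned node(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  ids <- sort(unique(memb[nm]))
  rows <- lapply(ids, function(id) {
    s <- score_cluster(g, nm[memb[nm] == id])
    data.frame(cluster = id, n_S = s$n_S, m_S = s$m_S, c_S = s$c_S,
               conductance = s$conductance, expansion = s$expansion)
  })
  do.call(rbind, rows)
}

#' Network community profile of a partition
#'
#' For every cluster size present, the best (minimum) conductance and
#' expansion among clusters of that size, plus the means over all clusters.
#'
#' @param g An undirected igraph graph with named vertices.
#' @param membership Named integer vector (or [core_partition]).
#' @return List of class `ncp_profile`: `profile` (data frame `size`,
#'   `best_conductance`, `best_expansion`, `n_clusters`), `scores` (the full
#'   [score_partition()] table), `mean_conductance`, `mean_expansion`.
#' @export
ncp_profile <- function(g, membership) {
  scores <- score_partition(g, membership)
  by_size <- split(scores, scores$n_S)
  prof <- do.call(rbind, lapply(by_size, function(d) {
    data.frame(size = d$n_S[1L],
               best_conductance = min(d$conductance),
               best_expansion = min(d$expansion),
               n_clusters = nrow(d))
  }))
  rownames(prof) <- NULL
  out <- list(profile = prof[order(prof$size), ], scores = scores,
              mean_conductance = mean(scores$conductance),
              mean_expansion = mean(scores$expansion))
  class(out) <- "ncp_profile"
  out
}

#' @export
print.ncp_profile <- function(x, ...) {
  cat("Network community profile (", nrow(x$scores), " clusters)\n", sep = "")
  cat(sprintf("  mean conductance %.6f, mean expansion %.6f\n",
              x$mean_conductance, x$mean_expansion))
  print(x$profile, row.names = FALSE)
  invisible(x)
}

#' Compare two algorithms' cluster-quality profiles
#'
#' Aligns the per-size best scores of two [ncp_profile()]s (or raw
#' [score_partition()] tables) on the cluster sizes present in both, and
#' reports, per metric, each algorithm's mean over its own clusters and the
#' fraction of common sizes at which A scores strictly lower (better) than B.
#' Sizes present in only one profile are listed but not counted.
#'
#' @param a,b `ncp_profile` objects or score data frames for algorithms A
#'   and B.
#' @return List of class `ncp_comparison`: `common` (data frame of per-size
#'   best scores for both), `only_a`, `only_b` (sizes unique to one profile),
#'   `mean_a`, `mean_b` (named: conductance, expansion),
#'   `win_fraction_conductance`, `win_fraction_expansion` (fraction of common
#'   sizes where A < B; `NA` when no common sizes).
#' @export
compare_partitions <- function(a, b) {
  pa <- if (inherits(a, "ncp_profile")) a else ncp_from_scores(a)
  pb <- if (inherits(b, "ncp_profile")) b else ncp_from_scores(b)
  if (nrow(pa$scores) == 0L || nrow(pb$scores) == 0L) {
    stop("compare_partitions: empty score table")
  }
  common_sizes <- intersect(pa$profile$size, pb$profile$size)
  ca <- pa$profile[match(common_sizes, pa$profile$size), ]
  cb <- pb$profile[match(common_sizes, pb$profile$size), ]
  common <- data.frame(size = common_sizes,
                       conductance_a = ca$best_conductance,
                       conductance_b = cb$best_conductance,
                       expansion_a = ca$best_expansion,
                       expansion_b = cb$best_expansion)
  wf <- function(x, y) if (length(x) == 0L) NA_real_ else mean(x < y)
  out <- list(
    common = common,
    only_a = setdiff(pa$profile$size, common_sizes),
    only_b = setdiff(pb$profile$size, common_sizes),
    mean_a = c(conductance = pa$mean_conductance,
               expansion = pa$mean_expansion),
    mean_b = c(conductance = pb$mean_conductance,
               expansion = pb$mean_expansion),
    win_fraction_conductance = wf(common$conductance_a, common$conductance_b),
    win_fraction_expansion = wf(common$expansion_a, common$expansion_b)
  )
  class(out) <- "ncp_comparison"
  out
}

ncp_from_scores <- function(scores) {
  stopifnot(is.data.frame(scores), nrow(scores) > 0L)
  by_size <- split(scores, scores$n_S)
  prof <- do.call(rbind, lapply(by_size, function(d) {
    data.frame(size = d$n_S[1L],
               best_conductance = min(d$conductance),
               best_expansion = min(d$expansion),
               n_clusters = nrow(d))
  }))
  rownames(prof) <- NULL
  structure(list(profile = prof[order(prof$size), ], scores = scores,
                 mean_conductance = mean(scores$conductance),
                 mean_expansion = mean(scores$expansion)),
            class = "ncp_profile")
}

#' @export
print.ncp_comparison <- function(x, ...) {
  cat("Cluster-quality comparison (A vs B)\n")
  cat(sprintf("  mean conductance: A %.6f  B %.6f\n",
              x$mean_a["conductance"], x$mean_b["conductance"]))
  cat(sprintf("  mean expansion:   A %.6f  B %.6f\n",
              x$mean_a["expansion"], x$mean_b["expansion"]))
  cat(sprintf("  A strictly better at %s of common sizes (conductance), %s (expansion)\n",
              format(x$win_fraction_conductance),
              format(x$win_fraction_expansion)))
  invisible(x)
}
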