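#' Centralization of a core-influence profile
#'
#' For a set of member scores with maximum C_A* and largest gap
#' D = max(C_A* - C_A(x)), the centralization is
#' sum(C_A* - C_A(x)) / ((n - 1) D). A uniform profile scores 0 ("no core");
#' a one-hot profile (one positive score, the rest zero) scores 1. Defined as
#' 0 for a single member or when all gaps vanish. Result lies in \[0, 1\].
#'
#' @param ca_values Numeric vector of core-influence values, one per member.
#' @return The centralization value.
#' @examples
#' centralization(c(1, 0, 0, 0)) # 1
#' centralization(c(0.3, 0.3))   # 0
#' centralization(c(0.6, 0.4, 0.2)) # 0.75
#' @export
centralization <- function(ca_values) {
  n <- length(ca_values)
  if (n == 0L) stop("centralization: empty profile")
  if (n == 1L) return(0)
  gaps <- max(ca_values) - ca_values
  d <- max(gaps)
  if (d == 0) return(0)
  sum(gaps) / ((n - 1) * d)
}

#' Total centralization of a partition
#'
#' Sum of [centralization()] over the nonempty clusters of a partition,
#' evaluated on the members' core-influence values. C_A values come from one
#' global computation on the full graph; they are never recomputed on
#' subgraphs.
#'
#' @param membership Named integer vector (or [core_partition]); nodes with
#'   `NA` assignment are ignored.
#' @param ca Named numeric vector of core-influence values covering all
#'   assigned nodes.
#' @return The summed centralization.
#' @export
total_centralization <- function(membership, ca) {
  memb <- as_membership(membership)
  memb <- memb[!is.na(memb)]
  if (length(memb) == 0L) return(0)
  vals <- ca[names(memb)]
  sum(vapply(split(vals, memb), centralization, numeric(1)))
}

#' Assign a contested or unclustered node to a cluster
#'
#' Candidate clusters are those containing at least one neighbour of the node
#' among the already-clustered nodes. The chosen cluster maximizes the total
#' centralization of the partition after tentatively adding the node
#' (a contested node is first removed from its provisional cluster). Ties are
#' broken by more edges from the node into the cluster, then by smaller
#' cluster id.
#'
#' @param node A node label.
#' @param membership Named integer vector with `NA` for unassigned nodes; the
#'   node's own entry may be `NA` (unclustered) or a provisional id
#'   (contested).
#' @param g The graph.
#' @param ca Named numeric core-influence vector.
#' @return The chosen cluster id, or `NA_integer_` if the node has no
#'   clustered neighbour (the caller defers).
#' @export
assign_contested <- function(node, membership, g, ca) {
  memb <- as_membership(membership)
  nbrs <- igraph::V(g)$name[igraph::neighbors(g, node)]
  cand <- sort(unique(memb[nbrs][!is.na(memb[nbrs])]))
  if (length(cand) == 0L) return(NA_integer_)
  current <- memb[[node]]
  pick_best_cluster(node, cand, current, memb, nbrs, ca)
}

# Shared candidate scorer. `memb` is the full named assignment (NA allowed),
# `current` the node's provisional cluster id or NA. Only affected clusters
# are re-evaluated; all others contribute a constant.
pick_best_cluster <- function(node, cand, current, memb, nbrs, ca) {
  affected <- sort(unique(c(cand, current[!is.na(current)])))
  member_sets <- lapply(affected, function(id) {
    setdiff(names(memb)[!is.na(memb) & memb == id], node)
  })
  names(member_sets) <- as.character(affected)
  score <- vapply(cand, function(id) {
    sum(vapply(affected, function(a) {
      s <- member_sets[[as.character(a)]]
      if (a == id) s <- c(s, node)
      if (length(s) == 0L) 0 else centralization(ca[s])
    }, numeric(1)))
  }, numeric(1))
  best <- score >= max(score) - 1e-12
  cand2 <- cand[best]
  if (length(cand2) > 1L) {
    e_in <- vapply(cand2, function(id) {
      sum(nbrs %in% member_sets[[as.character(id)]])
    }, numeric(1))
    cand2 <- cand2[e_in == max(e_in)]
  }
  as.integer(min(cand2))
}

#' Cluster a network by the core influence of its nodes
#'
#' The main fitting function. Per-node metrics are computed once on the full
#' graph; the top `core_fraction` of nodes under the configured ordering are
#' candidate cores. Every node starts unclustered (state Q). The first
#' candidate founds cluster 1 together with its neighbours. Each subsequent
#' candidate founds a new cluster if it is still unclustered, or — if it is
#' already clustered — secedes to found one exactly when its K value against
#' its current cluster falls in \[k_low, k_high\]; otherwise its unclustered
#' neighbours join its current cluster. Founding a cluster pulls the core's
#' unclustered neighbours in (state P) and marks its clustered neighbours
#' from other clusters as contested (state R, keeping their provisional
#' assignment). Contested nodes are resolved after each founding, in
#' decreasing core influence, by [assign_contested()] — the candidate cluster
#' maximizing total centralization wins. After the candidates are exhausted,
#' remaining unclustered nodes are resolved the same way in frontier sweeps;
#' nodes unreachable from any cluster found singleton clusters.
#'
#' Once every node is classified, a consolidation traversal corrects locally
#' misplaced nodes using the K statistic itself as the attachment measure:
#' each node, in decreasing core influence, moves to the adjacent cluster
#' maximizing its K value (only on strict improvement; ties broken by edge
#' count into the cluster, then smaller cluster id), and a cluster whose most
#' influential member is attached to an adjacent cluster above the
#' independence band (K > `k_high`) is merged into that cluster, weakest
#' core first, until no merge applies. The algorithm contains no randomness:
#' the same graph and parameters always yield the same partition.
#'
#' @param g An undirected igraph graph. Unnamed vertices are labelled by
#'   index.
#' @param params A [core_params()] list (K interval and candidate fraction).
#' @param order_by Candidate ordering key, see [candidate_cores()].
#' @param max_iter Cap on resolution/growth sweeps. Default 100.
#' @return An object of class `core_partition`; see [core_partition].
#' @examples
#' g <- igraph::make_full_graph(5)
#' fit <- influence_cluster(g)
#' fit$n_clusters # 1
#' @export
influence_cluster <- function(g, params = core_params(),
                              order_by = c("core_influence", "betweenness",
                                           "degree"),
                              max_iter = 100L) {
  order_by <- match.arg(order_by)
  if (igraph::vcount(g) == 0L) stop("influence_cluster: empty graph")
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  n <- igraph::vcount(g)
  labels <- igraph::V(g)$name
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  deg <- lengths(adj)
  m <- igraph::ecount(g)
  d_tot <- 2 * m

  metrics <- node_metrics(g)
  ca <- as.numeric(metrics$core_influence_vec)
  cands <- match(candidate_cores(metrics, params, order_by), labels)

  state <- rep("Q", n)          # Q unclustered, P clustered, R contested
  memb <- rep(NA_integer_, n)   # provisional for R, final for P
  is_core <- rep(FALSE, n)
  core_of <- integer(0)         # cluster id -> core node index
  next_id <- 0L
  founding_events <- 0L
  trace <- list()

  note <- function(event) {
    trace[[length(trace) + 1L]] <<- c(event = event,
                                      P = sum(state == "P"),
                                      Q = sum(state == "Q"),
                                      R = sum(state == "R"))
  }

  # order helper: core-influence descending, degree descending, label asc
  by_ca <- function(idx) idx[order(-ca[idx], -deg[idx], labels[idx])]

  k_value_of <- function(i) {
    members <- which(memb == memb[i] & state != "Q")
    d_q <- sum(deg[members])
    m_i <- sum(adj[[i]] %in% setdiff(members, i))
    d_i <- deg[i]
    if (d_i == 0L || d_i == d_tot || d_q == d_i) return(0)
    m_i / ((d_i / d_tot) * ((d_q - d_i) / (d_tot - d_i)) * m)
  }

  choose_for <- function(i) {
    nb <- adj[[i]]
    cand <- sort(unique(memb[nb][state[nb] == "P"]))
    if (length(cand) == 0L) return(NA_integer_)
    memb_named <- stats::setNames(memb, labels)
    pick_best_cluster(labels[i], cand, memb[i], memb_named,
                      labels[nb], stats::setNames(ca, labels))
  }

  found_cluster <- function(i) {
    next_id <<- next_id + 1L
    founding_events <<- founding_events + 1L
    id <- next_id
    memb[i] <<- id
    state[i] <<- "P"
    is_core[i] <<- TRUE
    core_of[id] <<- i
    for (j in adj[[i]]) {
      if (state[j] == "Q") {
        memb[j] <<- id
        state[j] <<- "P"
      } else if (state[j] == "P" && memb[j] != id && !is_core[j]) {
        state[j] <<- "R"   # contested; keeps provisional assignment
      }
    }
    note("found")
  }

  resolve_contested <- function() {
    iter <- 0L
    repeat {
      r_nodes <- by_ca(which(state == "R"))
      if (length(r_nodes) == 0L) return(invisible())
      iter <- iter + 1L
      progress <- FALSE
      for (i in r_nodes) {
        pick <- choose_for(i)
        if (is.na(pick)) next   # defer: no clustered neighbour yet
        memb[i] <<- pick
        state[i] <<- "P"
        progress <- TRUE
        note("resolve")
      }
      if (!progress || iter > max_iter) {
        # unreachable contested nodes keep their provisional cluster
        state[state == "R"] <<- "P"
        note("resolve")
        return(invisible())
      }
    }
  }

  for (ci in seq_along(cands)) {
    i <- cands[ci]
    if (founding_events == 0L || state[i] != "P") {
      found_cluster(i)
      resolve_contested()
    } else {
      kv <- k_value_of(i)
      if (kv >= params$k_low && kv <= params$k_high) {
        found_cluster(i)          # secession: leaves its old cluster
        resolve_contested()
      } else {
        qn <- adj[[i]][state[adj[[i]]] == "Q"]
        if (length(qn) > 0L) {
          memb[qn] <- memb[i]
          state[qn] <- "P"
          note("absorb")
        }
      }
    }
  }
  resolve_contested()

  # frontier sweeps: remaining unclustered nodes join an adjacent cluster
  # chosen by the centralization objective; nodes unreachable from any
  # cluster found singleton clusters that later sweeps can attach to
  sweeps <- 0L
  while (any(state == "Q")) {
    sweeps <- sweeps + 1L
    if (sweeps > max_iter) {
      warning("influence_cluster: frontier sweeps hit max_iter")
      break
    }
    progress <- FALSE
    for (i in by_ca(which(state == "Q"))) {
      pick <- choose_for(i)
      if (is.na(pick)) next
      memb[i] <- pick
      state[i] <- "P"
      progress <- TRUE
      note("sweep")
    }
    resolve_contested()
    if (!progress && any(state == "Q")) {
      i <- by_ca(which(state == "Q"))[1L]
      next_id <- next_id + 1L
      memb[i] <- next_id
      state[i] <- "P"
      is_core[i] <- TRUE
      core_of[next_id] <- i
      note("singleton")
    }
  }

  # ---- consolidation ------------------------------------------------------
  # The K statistic measures how strongly a node is attached to a cluster
  # relative to random wiring, so it drives the final traversal: (i)
  # attachment sweeps move each node to the adjacent cluster maximizing its
  # K value (strict improvement only); (ii) a cluster whose most influential
  # member is attached to an adjacent cluster above the independence band
  # (K > k_high) cannot head an independent cluster and merges into it.
  # Merges are self-limiting: growing a cluster raises the expected
  # connection count, lowering K against it.
  k_against <- function(i, cl) {
    members <- which(memb == cl)
    d_i <- deg[i]
    d_q <- sum(deg[members]) + if (memb[i] == cl) 0 else d_i
    m_i <- sum(adj[[i]] %in% setdiff(members, i))
    if (d_i == 0L || d_i == d_tot || d_q == d_i) return(0)
    m_i / ((d_i / d_tot) * ((d_q - d_i) / (d_tot - d_i)) * m)
  }
  full_order <- by_ca(seq_len(n))
  attachment_sweeps <- function() {
    for (s in seq_len(max_iter)) {
      changed <- FALSE
      for (i in full_order) {
        cls <- sort(unique(memb[adj[[i]]]))
        if (length(cls) == 0L) next
        ks <- vapply(cls, function(cl) k_against(i, cl), numeric(1))
        cur <- memb[i]
        best <- cls[ks >= max(ks) - 1e-12]
        if (length(best) > 1L) {
          e_in <- vapply(best, function(cl) sum(memb[adj[[i]]] == cl),
                         numeric(1))
          best <- best[e_in == max(e_in)]
        }
        b <- min(best)
        k_cur <- if (cur %in% cls) ks[match(cur, cls)] else k_against(i, cur)
        if (b != cur && max(ks) > k_cur + 1e-12) {
          memb[i] <<- b
          changed <- TRUE
        }
      }
      if (!changed) return(invisible())
      note("refine")
    }
    warning("influence_cluster: attachment sweeps hit max_iter")
  }
  cluster_core <- function(cl) {
    mem <- which(memb == cl)
    mem[order(-ca[mem], -deg[mem], labels[mem])][1L]
  }
  merge_round <- function() {
    alive <- sort(unique(memb))
    core_idx <- vapply(alive, cluster_core, integer(1))
    merged <- FALSE
    for (ci in order(ca[core_idx], labels[core_idx])) {  # weakest core first
      cl <- alive[ci]
      if (!(cl %in% memb)) next          # already merged away this round
      core_i <- cluster_core(cl)
      nb_cl <- setdiff(sort(unique(memb[adj[[core_i]]])), cl)
      if (length(nb_cl) == 0L) next
      ks <- vapply(nb_cl, function(t) k_against(core_i, t), numeric(1))
      if (max(ks) > params$k_high) {
        memb[memb == cl] <<- nb_cl[which.max(ks)]
        merged <- TRUE
        note("merge")
      }
    }
    merged
  }
  attachment_sweeps()
  merges <- 0L
  for (r in seq_len(max_iter)) {
    if (!merge_round()) break
    merges <- merges + 1L
    attachment_sweeps()
  }

  # final cores: the most influential member of each surviving cluster
  final_ids <- sort(unique(memb))
  core_of <- integer(max(final_ids))
  for (cl in final_ids) core_of[cl] <- cluster_core(cl)

  finalize_partition(g, memb, core_of, labels, metrics,
                     algorithm = "influence",
                     params = params, order_by = order_by,
                     founding_events = founding_events,
                     sweeps = sweeps, merges = merges, trace = trace)
}

# Relabel clusters 1..K by founding order and assemble the fit object.
finalize_partition <- function(g, memb, core_of, labels, metrics, algorithm,
                               params = NULL, order_by = NULL,
                               founding_events = NA_integer_,
                               sweeps = NA_integer_, merges = NA_integer_,
                               trace = list(), extra = list()) {
  used <- sort(unique(memb))
  relab <- match(memb, used)
  cores <- NULL
  if (length(core_of) > 0L) {
    keep <- which(!is.na(core_of[used]) & core_of[used] > 0L)
    cores <- stats::setNames(labels[core_of[used[keep]]],
                             as.character(keep))
  }
  membership <- stats::setNames(as.integer(relab), labels)
  tr <- if (length(trace) > 0L) {
    df <- as.data.frame(do.call(rbind, trace), stringsAsFactors = FALSE)
    df$P <- as.integer(df$P); df$Q <- as.integer(df$Q)
    df$R <- as.integer(df$R)
    df
  } else NULL
  out <- c(list(
    membership = membership,
    cores = cores,
    n_clusters = length(used),
    sizes = as.integer(table(relab)),
    algorithm = algorithm,
    params = params,
    order_by = order_by,
    founding_events = founding_events,
    sweeps = sweeps,
    merges = merges,
    trace = tr,
    metrics = metrics,
    graph = g
  ), extra)
  class(out) <- "core_partition"
  out
}

#' Fitted network partition
#'
#' Objects of class `core_partition` are returned by [influence_cluster()]
#' and [fast_newman()]. Fields: `membership` (named integer vector, cluster
#' ids 1..K), `cores` (cluster id -> core label: the most influential member
#' of each final cluster, influence algorithm only), `n_clusters`, `sizes`,
#' `algorithm`, `founding_events`, `sweeps`, `merges`, `trace` (per-event
#' P/Q/R state counts), `metrics` (the [node_metrics()] used), and the
#' fitted `graph`. The Fast-Newman fit additionally carries `q_trace`
#' (modularity after every merge) and `peak_q`.
#'
#' @name core_partition
NULL

#' @export
print.core_partition <- function(x, ...) {
  cat("Network partition (", x$algorithm, " algorithm)\n", sep = "")
  cat("  ", length(x$membership), " nodes in ", x$n_clusters,
      " clusters; sizes: ",
      paste(sort(x$sizes, decreasing = TRUE), collapse = " "), "\n", sep = "")
  if (!is.null(x$peak_q)) cat(sprintf("  peak modularity Q = %.6f\n",
                                      x$peak_q))
  if (!is.null(x$cores)) {
    cat("  cores: ", paste(sprintf("%s:%s", names(x$cores), x$cores),
                           collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.core_partition <- function(object, ...) {
  scores <- score_partition(object$graph, object$membership)
  out <- list(fit = object, scores = scores,
              mean_conductance = mean(scores$conductance),
              mean_expansion = mean(scores$expansion))
  class(out) <- "summary.core_partition"
  out
}

#' @export
print.summary.core_partition <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  mean conductance: %.6f  mean expansion: %.6f\n",
              x$mean_conductance, x$mean_expansion))
  cat("  per-cluster scores:\n")
  print(x$scores, row.names = FALSE)
  invisible(x)
}

#' @export
plot.core_partition <- function(x, ...) {
  cols <- grDevices::rainbow(x$n_clusters)
  igraph::plot.igraph(x$graph,
                      vertex.color = cols[x$membership[igraph::V(x$graph)$name]],
                      vertex.size = 6, vertex.label.cex = 0.6, ...)
  invisible(x)
}
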