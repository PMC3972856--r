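#' Read an undirected graph from a whitespace-delimited edge list
#'
#' Each non-comment line names one edge by its two endpoint labels; extra
#' tokens on a line are ignored. Lines starting with `#` or `%` are comments.
#' The result is always a simple undirected graph: duplicate lines collapse to
#' one edge and, with `drop_self_loops = TRUE` (the default), self-loop lines
#' are discarded with a message reporting how many were dropped.
#'
#' @param path Path to the edge-list file.
#' @param symmetrize Treat lines as unordered pairs (always the case for an
#'   undirected result; kept as an explicit switch for clarity). Default `TRUE`.
#' @param drop_self_loops Drop lines whose two endpoints are equal. Default
#'   `TRUE`; with `FALSE`, a self-loop line raises an error since the graphs
#'   handled here are simple.
#' @return An undirected simple [igraph][igraph::igraph-package] graph whose
#'   vertices carry the file's labels as names.
#' @examples
#' f <- tempfile()
#' writeLines(c("# toy", "a b", "b c"), f)
#' g <- read_edge_list(f)
#' igraph::vcount(g) # 3
#' @export
read_edge_list <- function(path, symmetrize = TRUE, drop_self_loops = TRUE) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*($|#|%)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(lengths(toks) < 2L)
  if (length(bad) > 0L) {
    stop("malformed edge list line ", idx[bad[1L]], " in ", path,
         ": expected at least two whitespace-separated tokens")
  }
  ends <- t(vapply(toks, function(tk) tk[1:2], character(2)))
  loops <- ends[, 1L] == ends[, 2L]
  if (any(loops)) {
    if (!drop_self_loops) {
      stop("self-loop on line ", idx[which(loops)[1L]], " in ", path)
    }
    message("read_edge_list: dropped ", sum(loops), " self-loop line(s)")
    ends <- ends[!loops, , drop = FALSE]
  }
  labels <- sort(unique(as.vector(ends)))
  g <- igraph::graph_from_edgelist(ends, directed = !symmetrize)
  g <- igraph::as_undirected(g, mode = "collapse")
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  # deterministic vertex order: lexicographic labels
  igraph::permute(g, match(igraph::V(g)$name, labels))
}

#' Read an undirected graph from a GML file
#'
#' Node labels are taken from the GML `label` attribute when present,
#' otherwise from the stringified `id`. Directed GML files are symmetrized;
#' multi-edges are collapsed and self-loops removed, so the result is a simple
#' undirected graph.
#'
#' @param path Path to the GML file.
#' @return An undirected simple igraph graph with named vertices.
#' @export
read_gml <- function(path) {
  if (!file.exists(path)) stop("GML file not found: ", path)
  g <- tryCatch(
    igraph::read_graph(path, format = "gml"),
    error = function(e) stop("GML format error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  va <- igraph::vertex_attr_names(g)
  if ("label" %in% va) {
    igraph::V(g)$name <- as.character(igraph::V(g)$label)
  } else if ("id" %in% va) {
    igraph::V(g)$name <- as.character(igraph::V(g)$id)
  } else if (!("name" %in% va)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)) - 1L)
  }
  g <- igraph::as_undirected(g, mode = "collapse")
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  labels <- sort(igraph::V(g)$name)
  igraph::permute(g, match(igraph::V(g)$name, labels))
}

#' Write a partition to a two-column TSV file
#'
#' One row per node — node label, integer cluster id — sorted by node label.
#' Round-trips through [read_partition()].
#'
#' @param partition A named integer vector mapping node label to cluster id,
#'   or a [core_partition] object (its membership is written).
#' @param path Output file path.
#' @param graph Optional graph; when supplied, every vertex must be assigned
#'   or an integrity error is raised.
#' @return Invisibly, the path.
#' @export
write_partition <- function(partition, path, graph = NULL) {
  memb <- as_membership(partition)
  if (anyNA(memb)) stop("integrity error: partition contains unassigned nodes")
  if (!is.null(graph)) {
    missing <- setdiff(igraph::V(graph)$name, names(memb))
    if (length(missing) > 0L) {
      stop("integrity error: nodes missing from partition: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
  }
  ord <- order(names(memb))
  df <- data.frame(node = names(memb)[ord],
                   cluster = as.integer(memb[ord]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a partition from a two-column TSV file
#'
#' Inverse of [write_partition()]. Cluster ids need not be contiguous.
#'
#' @param path Path to a TSV with columns node, cluster (a header row named
#'   `node` is detected and skipped).
#' @return Named integer vector mapping node label to cluster id.
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop("partition file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer"),
                          col.names = c("node", "cluster"))
  if (anyDuplicated(df$node)) {
    stop("integrity error: duplicate node row(s) in ", path, ": ",
         df$node[anyDuplicated(df$node)])
  }
  stats::setNames(as.integer(df$cluster), df$node)
}

#' Descriptive summary statistics of a graph
#'
#' The six headline descriptive properties of a network: node count, edge
#' count, triangle count, average local clustering coefficient (nodes of
#' degree < 2 contribute 0), and the diameter and mean shortest-path length of
#' the largest connected component (unweighted hop counts, mean over unordered
#' connected pairs).
#'
#' @param g An undirected igraph graph.
#' @return A list of class `graph_summary` with fields `n_nodes`, `n_edges`,
#'   `n_triangles`, `avg_clustering`, `diameter`, `avg_shortest_path`.
#' @examples
#' graph_summary(igraph::make_full_graph(3))
#' @export
graph_summary <- function(g) {
  if (igraph::vcount(g) == 0L) stop("graph_summary: empty graph")
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  out <- list(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    n_triangles = sum(igraph::count_triangles(g)) / 3L,
    avg_clustering = mean(cc),
    diameter = if (igraph::vcount(giant) > 1L)
      igraph::diameter(giant, unconnected = FALSE) else 0,
    avg_shortest_path = if (igraph::vcount(giant) > 1L)
      igraph::mean_distance(giant) else 0
  )
  class(out) <- "graph_summary"
  out
}

#' @export
print.graph_summary <- function(x, ...) {
  cat("Graph summary\n")
  cat(sprintf("  nodes: %d  edges: %d  triangles: %d\n",
              x$n_nodes, x$n_edges, as.integer(round(x$n_triangles))))
  cat(sprintf("  average clustering coefficient: %.4f\n", x$avg_clustering))
  cat(sprintf("  diameter: %d  average shortest path: %.4f\n",
              as.integer(x$diameter), x$avg_shortest_path))
  invisible(x)
}

# Coerce a partition-like object to a named membership vector.
as_membership <- function(x) {
  if (inherits(x, "core_partition")) return(x$membership)
  if (is.null(names(x))) stop("partition must be named by node label")
  stats::setNames(as.integer(x), names(x))
}
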