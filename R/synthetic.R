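#' Generate a planted-partition benchmark graph
#'
#' Blocks of equal size with independent Bernoulli edges: probability `p_in`
#' within a block, `p_out` between blocks. The ground-truth block labels are
#' returned with the graph, so recovery can be scored with [nmi()].
#' Deterministic given `seed`.
#'
#' @param n_blocks Number of blocks (>= 2).
#' @param block_size Nodes per block (>= 2).
#' @param p_in Intra-block edge probability.
#' @param p_out Inter-block edge probability; must satisfy
#'   0 <= p_out < p_in <= 1.
#' @param seed Integer seed for the edge draw.
#' @return List with `graph` (igraph, named vertices) and `truth` (named
#'   integer vector of block labels).
#' @examples
#' pp <- planted_partition(4, 25, 0.3, 0.02, seed = 1)
#' igraph::vcount(pp$graph) # 100
#' @export
planted_partition <- function(n_blocks, block_size, p_in, p_out, seed) {
  if (!(n_blocks >= 2L)) stop("planted_partition: need n_blocks >= 2")
  if (!(block_size >= 2L)) stop("planted_partition: need block_size >= 2")
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop("planted_partition: need 0 <= p_out < p_in <= 1")
  }
  n <- n_blocks * block_size
  pref <- matrix(p_out, n_blocks, n_blocks)
  diag(pref) <- p_in
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  g <- igraph::sample_sbm(n, pref.matrix = pref,
                          block.sizes = rep(block_size, n_blocks))
  labels <- sprintf("v%0*d", nchar(n), seq_len(n))
  igraph::V(g)$name <- labels
  truth <- stats::setNames(rep(seq_len(n_blocks), each = block_size), labels)
  list(graph = g, truth = truth)
}

#' Normalized mutual information between two partitions
#'
#' NMI = 2 I(A; B) / (H(A) + H(B)) over the joint label contingency table;
#' 1 iff the partitions are identical up to relabelling. Conventions for
#' degenerate entropies: when both partitions are single-cluster the NMI is 1;
#' when exactly one has zero entropy it is 0.
#'
#' @param a,b Named label vectors (or [core_partition] objects) over the same
#'   node set.
#' @return NMI value in \[0, 1\].
#' @examples
#' nmi(c(x = 1, y = 1, z = 2), c(x = 5, y = 5, z = 9)) # 1
#' @export
nmi <- function(a, b) {
  ma <- as_membership(a)
  mb <- as_membership(b)
  if (!setequal(names(ma), names(mb))) {
    stop("nmi: partitions are over different node sets")
  }
  mb <- mb[names(ma)]
  n <- length(ma)
  tab <- table(ma, mb) / n
  pa <- rowSums(tab)
  pb <- colSums(tab)
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ha <- h(pa)
  hb <- h(pb)
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  pij <- as.numeric(tab)
  eij <- as.numeric(outer(pa, pb))
  pos <- pij > 0
  i_ab <- sum(pij[pos] * log(pij[pos] / eij[pos]))
  2 * i_ab / (ha + hb)
}

#' Mean planted-partition recovery over repeated draws
#'
#' Convenience wrapper: generates `n_seeds` planted-partition graphs
#' (seeds `seed_start`, `seed_start + 1`, ...), clusters each with
#' [influence_cluster()], and returns the NMI against ground truth for each
#' draw.
#'
#' @inheritParams planted_partition
#' @param n_seeds Number of independent draws.
#' @param seed_start First seed.
#' @param ... Passed to [influence_cluster()].
#' @return Numeric vector of NMI values, one per seed.
#' @export
recovery_nmi <- function(n_blocks, block_size, p_in, p_out,
                         n_seeds = 20L, seed_start = 1L, ...) {
  vapply(seq_len(n_seeds), function(k) {
    pp <- planted_partition(n_blocks, block_size, p_in, p_out,
                            seed = seed_start + k - 1L)
    fit <- influence_cluster(pp$graph, ...)
    nmi(fit$membership, pp$truth)
  }, numeric(1))
}
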