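#' Degree distribution with the single-partner self-loop convention
#'
#' Degrees count the number of distinct binding partners per node, so a
#' self-loop contributes 1 to the degree of its node (not the
#' graph-theoretic 2): a self-binding interface has itself as one partner.
#' Parallel edges are rejected.
#'
#' @param graph an igraph graph, \linkS4class{IIN} or
#'   \linkS4class{PPINetwork}.
#' @return list with \code{degrees} (named per node), \code{k},
#'   \code{p_of_k} (the degree distribution p(k)), and \code{mean_degree}.
#' @examples
#' g <- igraph::make_ring(3)
#' degreeDistribution(g)$mean_degree   # 2
#' @export
degreeDistribution <- function(graph) {
  g <- asGraph(graph)
  if (igraph::any_multiple(g))
    stop("graph has parallel edges")
  deg <- nodeDegrees(g)
  tab <- table(deg)
  k <- as.integer(names(tab))
  p <- as.numeric(tab) / length(deg)
  list(degrees = deg, k = k, p_of_k = p, mean_degree = mean(deg))
}

## degree per node, counting a self-loop once
nodeDegrees <- function(g) {
  deg <- igraph::degree(igraph::simplify(g, remove.multiple = FALSE,
                                         remove.loops = TRUE))
  loops <- igraph::which_loop(g)
  if (any(loops)) {
    loop_nodes <- igraph::ends(g, igraph::E(g)[loops])[, 1]
    deg[unique(loop_nodes)] <- deg[unique(loop_nodes)] + 1L
  }
  deg
}

#' Local and global clustering coefficients
#'
#' C(i) = N_closed(i) / [k(i)(k(i)-1)/2], the fraction of a node's partner
#' pairs that are themselves connected; self-loops are ignored throughout.
#' The global coefficient is computed over distinct 3-node sets:
#' N_triangle / (N_triangle + N_open), where N_open counts distinct
#' connected open triplets, so one triangle contributes a single closed
#' triplet (this differs from the 3x-triangle transitivity ratio).  Nodes
#' with fewer than two partners have no partner pairs; by default they are
#' excluded from the local mean, or counted as 0 with
#' \code{include_low_degree = TRUE}.
#'
#' @param graph an igraph graph, \linkS4class{IIN} or
#'   \linkS4class{PPINetwork}.
#' @param include_low_degree count k < 2 nodes as C(i) = 0 in the mean?
#' @return list with \code{c_local_per_node}, \code{c_local_mean},
#'   \code{c_global}, \code{n_triangle}, \code{n_open}.
#' @examples
#' clusteringCoefficients(igraph::make_full_graph(4))$c_global   # 1
#' @export
clusteringCoefficients <- function(graph, include_low_degree = FALSE) {
  g <- igraph::simplify(asGraph(graph), remove.loops = TRUE,
                        remove.multiple = TRUE)
  deg <- igraph::degree(g)
  tri <- igraph::count_triangles(g)
  pairs <- deg * (deg - 1) / 2
  c_local <- ifelse(pairs > 0, tri / pairs, NA_real_)
  names(c_local) <- igraph::V(g)$name
  if (include_low_degree) {
    vals <- ifelse(is.na(c_local), 0, c_local)
    c_mean <- if (length(vals)) mean(vals) else NaN
  } else {
    c_mean <- if (any(!is.na(c_local))) mean(c_local, na.rm = TRUE) else 0
  }
  n_tri <- sum(tri) / 3
  ## distinct open triplets = all center-counted paths minus the 3 closed
  ## ones each triangle accounts for
  n_open <- sum(pairs) - 3 * n_tri
  c_global <- if (n_tri + n_open > 0) n_tri / (n_tri + n_open) else 0
  list(c_local_per_node = c_local, c_local_mean = c_mean,
       c_global = c_global, n_triangle = n_tri, n_open = n_open)
}

#' Module (connected component) size distribution
#'
#' A module is a connected fragment of the network; its size is its node
#' count (for an IIN, the number of interfaces).  Because module samples
#' are small, the cumulative distribution is reported as
#' P(m) = fraction of modules of size >= m.
#'
#' @param graph an igraph graph, \linkS4class{IIN} or
#'   \linkS4class{PPINetwork}.
#' @return list with \code{sizes} (one entry per module), \code{m} and
#'   \code{cumulative} (P(m) at each observed size).
#' @export
connectedModules <- function(graph) {
  g <- asGraph(graph)
  comp <- igraph::components(g)
  sizes <- as.integer(comp$csize)
  m <- sort(unique(sizes))
  cumulative <- vapply(m, function(mm) mean(sizes >= mm), numeric(1))
  list(sizes = sizes, m = m, cumulative = cumulative)
}

#' Hypergeometric tail probability
#'
#' P(X >= x) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least x positives when n items are drawn without replacement from a
#' population of N containing K positives.  Used for enrichment questions
#' such as whether a trait is over-represented in a protein subset.
#' Computed by summing exact \code{stats::dhyper} terms (evaluated in
#' log space and combined stably), so small tails like the per-mille range
#' are exact to double precision.
#'
#' @param population N, population size.
#' @param positives K, number of positives in the population.
#' @param draws n, number drawn.
#' @param threshold x, minimum number of positives drawn.
#' @return P(X >= x).
#' @examples
#' hypergeomTail(56, 22, 9, 8)   # ~0.0015
#' @export
hypergeomTail <- function(population, positives, draws, threshold) {
  N <- population; K <- positives; n <- draws; x <- threshold
  if (any(c(N, K, n, x) != round(c(N, K, n, x))))
    stop("all parameters must be integers")
  if (K < 0 || K > N || n < 0 || n > N || x < 0 || x > n)
    stop("require 0 <= x <= n <= N and 0 <= K <= N")
  if (x == 0) return(1)
  xs <- x:min(n, K)
  if (!length(xs)) return(0)
  lp <- stats::dhyper(xs, K, N - K, n, log = TRUE)
  lmax <- max(lp)
  exp(lmax) * sum(exp(lp - lmax))
}
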