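#' Classify one connected 4-node induced subgraph
#'
#' The six mutually exclusive architectures of a connected induced 4-node
#' subgraph: with 3 edges, \code{hub} (a star -- some node touches the
#' other three) or \code{chain} (a path); with 4 edges, \code{square} (the
#' chordless 4-cycle, all degrees 2) or \code{flag} (a triangle with a
#' pendant edge); with 5 edges \code{diamond5}; with 6 edges
#' \code{clique6}.  Self-loops are stripped before counting.
#'
#' @param subgraph an igraph graph on exactly 4 nodes.
#' @return one of \code{\link{motifClasses}}.
#' @examples
#' classifyMotif4(igraph::make_ring(4))   # "square"
#' @export
classifyMotif4 <- function(subgraph) {
  g <- igraph::simplify(asGraph(subgraph), remove.loops = TRUE,
                        remove.multiple = TRUE)
  if (igraph::vcount(g) != 4L)
    stop("subgraph must have exactly 4 nodes")
  if (igraph::components(g)$no != 1L)
    stop("subgraph is not connected")
  ne <- igraph::ecount(g)
  deg <- igraph::degree(g)
  switch(as.character(ne),
         "3" = if (max(deg) == 3L) "hub" else "chain",
         "4" = if (all(deg == 2L)) "square" else "flag",
         "5" = "diamond5",
         "6" = "clique6",
         stop("internal error: connected 4-node graph with ", ne, " edges"))
}

#' Exact census of connected 4-node motifs
#'
#' Enumerates every 4-node subset of the graph whose induced subgraph is
#' connected and classifies each subset into exactly one of the six motif
#' classes.  Self-loops are dropped first (they carry no meaning inside a
#' 4-node architecture).  The default backend is igraph's exact
#' subgraph-enumeration machinery; \code{method = "enumerate"} runs this
#' package's neighborhood-expansion enumerator instead (identical results,
#' usable as a cross-check and on graphs igraph cannot handle).
#'
#' @param graph an igraph graph, \linkS4class{IIN} or
#'   \linkS4class{PPINetwork}.
#' @param method \code{"igraph"} (default) or \code{"enumerate"}.
#' @return A \linkS4class{MotifCensus}.
#' @examples
#' motifCounts(motifCensus4(igraph::make_star(5, mode = "undirected")))
#' @export
motifCensus4 <- function(graph, method = c("igraph", "enumerate")) {
  method <- match.arg(method)
  g <- igraph::simplify(asGraph(graph), remove.loops = TRUE,
                        remove.multiple = TRUE)
  counts <- stats::setNames(integer(6), motifClasses())
  if (method == "igraph" && igraph::vcount(g) >= 4L) {
    raw <- igraph::motifs(g, size = 4)
    map <- isoclassMap()
    for (cls in names(map))
      counts[cls] <- sum(raw[map[[cls]] + 1L], na.rm = TRUE)
    counts <- as.integer(counts)
    names(counts) <- motifClasses()
  } else if (method == "enumerate") {
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
    for (sub in connectedQuads(g)) {
      cls <- classifyQuadDegrees(adj, sub)
      counts[[cls]] <- counts[[cls]] + 1L
    }
  }
  total <- sum(counts)
  fractions <- if (total > 0) counts / total else numeric(6)
  new("MotifCensus", counts = counts,
      fractions = stats::setNames(as.numeric(fractions), motifClasses()),
      total = as.integer(total))
}

## classify the induced subgraph on vertex ids `sub` from a logical
## adjacency matrix, without building an igraph object
classifyQuadDegrees <- function(adj, sub) {
  a <- adj[sub, sub]
  ne <- sum(a) / 2
  deg <- rowSums(a)
  if (ne == 3) { if (max(deg) == 3) "hub" else "chain" }
  else if (ne == 4) { if (all(deg == 2)) "square" else "flag" }
  else if (ne == 5) "diamond5"
  else "clique6"
}

## ESU-style enumeration of all connected 4-node subsets (each exactly once):
## grow from each root using only higher-numbered vertices in the exclusive
## neighborhood of the current subset
connectedQuads <- function(g) {
  n <- igraph::vcount(g)
  if (n < 4L) return(list())
  nbrs <- lapply(seq_len(n), function(v)
    as.integer(igraph::neighbors(g, v)))
  out <- list()
  extend <- function(sub, ext, root) {
    if (length(sub) == 4L) {
      out[[length(out) + 1L]] <<- sub
      return(invisible())
    }
    while (length(ext)) {
      w <- ext[[1L]]
      ext <- ext[-1L]
      new_ext <- setdiff(nbrs[[w]], c(sub, w, unlist(nbrs[sub]), root))
      new_ext <- new_ext[new_ext > root]
      extend(c(sub, w), c(ext, new_ext), root)
    }
  }
  for (v in seq_len(n)) {
    ext <- nbrs[[v]][nbrs[[v]] > v]
    extend(v, ext, v)
  }
  out
}

## map motif class -> igraph undirected-size-4 isoclass indices (0-based),
## computed once from representative graphs and cached
.iinet_cache <- new.env(parent = emptyenv())

isoclassMap <- function() {
  if (!is.null(.iinet_cache$isoclass_map))
    return(.iinet_cache$isoclass_map)
  reps <- list(
    hub = c(1, 2, 1, 3, 1, 4),
    chain = c(1, 2, 2, 3, 3, 4),
    flag = c(1, 2, 2, 3, 3, 1, 3, 4),
    square = c(1, 2, 2, 3, 3, 4, 4, 1),
    diamond5 = c(1, 2, 2, 3, 3, 1, 3, 4, 4, 1),
    clique6 = c(1, 2, 1, 3, 1, 4, 2, 3, 2, 4, 3, 4))
  map <- lapply(reps, function(ed) {
    g <- igraph::make_graph(ed, n = 4, directed = FALSE)
    igraph::isomorphism_class(g)
  })
  .iinet_cache$isoclass_map <- map
  map
}
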