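## Brute-force oracles, kept deliberately naive and independent of the
## package's implementation paths.

## seeded Erdos-Renyi graph
randomGraph <- function(n, p, seed) {
  set.seed(seed)
  igraph::sample_gnp(n, p)
}

## exhaustive clique test: is every pair inside `idx` connected by a 1?
oracleIsClique <- function(m, idx) {
  if (length(idx) < 2L) return(TRUE)
  for (i in seq_len(length(idx) - 1L))
    for (j in (i + 1L):length(idx))
      if (m[idx[i], idx[j]] != 1L) return(FALSE)
  TRUE
}

## components of the entry==1 relation by naive repeated expansion
oracleOverlapComponents <- function(m) {
  k <- nrow(m)
  comp <- seq_len(k)
  repeat {
    changed <- FALSE
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i != j && isTRUE(m[i, j] == 1L) && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(seq_len(k), comp)
}

## clustering by enumerating every 3-node subset
oracleClustering <- function(g) {
  g <- igraph::simplify(g, remove.loops = TRUE)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  n <- nrow(adj)
  n_tri <- 0; n_open <- 0
  if (n >= 3) {
    for (s in utils::combn(n, 3, simplify = FALSE)) {
      e <- sum(adj[s[1], s[2]], adj[s[1], s[3]], adj[s[2], s[3]])
      if (e == 3) n_tri <- n_tri + 1
      else if (e == 2) n_open <- n_open + 1
    }
  }
  c_local <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ])
    if (length(nb) < 2) next
    closed <- 0
    for (pq in utils::combn(nb, 2, simplify = FALSE))
      closed <- closed + adj[pq[1], pq[2]]
    c_local[i] <- closed / choose(length(nb), 2)
  }
  list(n_triangle = n_tri, n_open = n_open,
       c_global = if (n_tri + n_open > 0) n_tri / (n_tri + n_open) else 0,
       c_local_mean = if (any(!is.na(c_local)))
         mean(c_local, na.rm = TRUE) else 0)
}

## motif census by testing every one of the C(n,4) subsets, classifying by
## isomorphism against reference graphs
motifReferenceGraphs <- function() {
  list(hub = igraph::make_graph(c(1, 2, 1, 3, 1, 4), n = 4, directed = FALSE),
       chain = igraph::make_graph(c(1, 2, 2, 3, 3, 4), n = 4,
                                  directed = FALSE),
       flag = igraph::make_graph(c(1, 2, 2, 3, 3, 1, 3, 4), n = 4,
                                 directed = FALSE),
       square = igraph::make_ring(4),
       diamond5 = igraph::make_graph(c(1, 2, 2, 3, 3, 1, 3, 4, 4, 1), n = 4,
                                     directed = FALSE),
       clique6 = igraph::make_full_graph(4))
}

oracleCensus4 <- function(g) {
  g <- igraph::simplify(g, remove.loops = TRUE)
  refs <- motifReferenceGraphs()
  counts <- stats::setNames(integer(6), names(refs))
  n <- igraph::vcount(g)
  if (n >= 4) {
    for (s in utils::combn(n, 4, simplify = FALSE)) {
      sub <- igraph::induced_subgraph(g, s)
      if (igraph::components(sub)$no != 1L) next
      for (nm in names(refs)) {
        if (igraph::isomorphic(sub, refs[[nm]])) {
          counts[nm] <- counts[nm] + 1L
          break
        }
      }
    }
  }
  counts
}

## connected components by naive BFS labelling
oracleComponentSizes <- function(g) {
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  sizes <- integer(0)
  for (v in seq_len(n)) {
    if (seen[v]) next
    queue <- v
    seen[v] <- TRUE
    size <- 0L
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      size <- size + 1L
      nb <- which(adj[u, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    sizes <- c(sizes, size)
  }
  sort(sizes)
}

## hypergeometric tail by enumerating every possible draw
oracleHyperTail <- function(N, K, n, x) {
  draws <- utils::combn(N, n, simplify = FALSE)
  hits <- vapply(draws, function(d) sum(d <= K) >= x, logical(1))
  mean(hits)
}

## tiny synthetic instance for round-trip style tests
smallSpec <- function(seed, n = 12) {
  syntheticSpec(n_proteins = n, seed = seed)
}

## a PPI + all-distinct overlap matrices with prescribed mode multiplicities
ppiWithModes <- function(n_edges, n_two, n_three, n_proteins = 30) {
  prot <- sprintf("Q%03d", seq_len(n_proteins))
  pairs <- t(utils::combn(prot, 2))[seq_len(n_edges), , drop = FALSE]
  n_modes <- rep(1L, n_edges)
  if (n_two) n_modes[seq_len(n_two)] <- 2L
  if (n_three) n_modes[n_two + seq_len(n_three)] <- 3L
  edges <- data.frame(a = pairs[, 1], b = pairs[, 2],
                      support_class = "assigned", n_modes = n_modes,
                      references = "", stringsAsFactors = FALSE)
  ppi <- PPINetwork(edges, proteins = data.frame(id = prot))
  mats <- lapply(prot, function(p) {
    inc <- edges[edges$a == p | edges$b == p, , drop = FALSE]
    if (!nrow(inc)) return(NULL)
    labels <- unlist(lapply(seq_len(nrow(inc)), function(i) {
      q <- if (inc$a[i] == p) inc$b[i] else inc$a[i]
      if (inc$n_modes[i] == 1L) q else paste0(q, "@", seq_len(inc$n_modes[i]))
    }))
    m <- matrix(0L, length(labels), length(labels),
                dimnames = list(labels, labels))
    OverlapMatrix(p, m)
  })
  list(ppi = ppi, matrices = Filter(Negate(is.null), mats))
}
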