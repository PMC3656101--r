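## evaluate `code` under a fixed RNG seed without disturbing the caller's
## RNG state
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Degree-preserving randomization by Maslov-Sneppen edge swapping
#'
#' Rewires a network while preserving every node's degree (with the
#' single-partner self-loop convention).  A trial move picks two nodes at
#' random, one neighbor of each at random, and swaps the two partners
#' between the nodes; the move is rejected if a produced edge already
#' exists, would duplicate the other produced edge, or would create a new
#' self-loop.  Pre-existing self-loops are frozen: they are excluded from
#' the swappable pool and survive unchanged, which keeps the degree
#' multiset exactly conserved.  The chain runs until \code{n_accepted}
#' swap acceptances.
#'
#' @param graph an igraph graph, \linkS4class{IIN} or
#'   \linkS4class{PPINetwork}.
#' @param n_accepted number of accepted swaps (default 10 per swappable
#'   edge).
#' @param seed integer RNG seed; required, so no run depends on implicit
#'   global state.
#' @param max_trials safety cap on trial moves (default 1000 x
#'   \code{n_accepted}).
#' @return an igraph graph on the same vertex set with the same degree
#'   multiset.
#' @examples
#' g <- igraph::sample_gnp(20, 0.2)
#' r <- maslovSneppen(g, seed = 1)
#' identical(sort(igraph::degree(g)), sort(igraph::degree(r)))
#' @export
maslovSneppen <- function(graph, n_accepted = NULL, seed,
                          max_trials = NULL) {
  g <- asGraph(graph)
  if (missing(seed)) stop("an explicit `seed` is required")
  ends <- igraph::as_edgelist(g, names = FALSE)
  loop <- ends[, 1] == ends[, 2]
  loops <- ends[loop, , drop = FALSE]
  ends <- ends[!loop, , drop = FALSE]
  if (nrow(ends) < 2L)
    stop("need at least 2 swappable (non-loop) edges")
  if (is.null(n_accepted)) n_accepted <- 10L * nrow(ends)
  if (is.null(max_trials)) max_trials <- 1000L * max(1L, n_accepted)
  n <- igraph::vcount(g)
  withSeed(seed, {
    ## adjacency of swappable edges
    A <- matrix(FALSE, n, n)
    A[ends] <- TRUE
    A[ends[, 2:1, drop = FALSE]] <- TRUE
    adj <- lapply(seq_len(n), function(v) which(A[v, ]))
    sel <- which(lengths(adj) > 0L)
    accepted <- 0L
    trials <- 0L
    while (accepted < n_accepted) {
      trials <- trials + 1L
      if (trials > max_trials)
        stop("swap chain exceeded max_trials (", max_trials,
             ") before reaching ", n_accepted, " acceptances; ",
             "the graph may be too rigid to rewire")
      ab <- sel[sample.int(length(sel), 2L, replace = TRUE)]
      a <- ab[1L]; b <- ab[2L]
      if (a == b) next
      x <- adj[[a]][sample.int(length(adj[[a]]), 1L)]
      y <- adj[[b]][sample.int(length(adj[[b]]), 1L)]
      ## proposed new edges: a-y and b-x
      if (a == y || b == x) next           # would create a self-loop
      if (x == y) next                      # both new edges would coincide
      if (A[a, y] || A[b, x]) next          # would duplicate existing edge
      A[a, x] <- A[x, a] <- FALSE
      A[b, y] <- A[y, b] <- FALSE
      A[a, y] <- A[y, a] <- TRUE
      A[b, x] <- A[x, b] <- TRUE
      adj[[a]] <- c(adj[[a]][adj[[a]] != x], y)
      adj[[x]] <- c(adj[[x]][adj[[x]] != a], b)
      adj[[b]] <- c(adj[[b]][adj[[b]] != y], x)
      adj[[y]] <- c(adj[[y]][adj[[y]] != b], a)
      accepted <- accepted + 1L
    }
    new_ends <- which(A & upper.tri(A), arr.ind = TRUE)
    all_ends <- rbind(new_ends, loops)
    out <- igraph::make_empty_graph(n, directed = FALSE)
    out <- igraph::add_edges(out, t(all_ends))
    if (!is.null(igraph::V(g)$name))
      igraph::V(out)$name <- igraph::V(g)$name
    out
  })
}

#' Null ensembles and empirical p-values for graph statistics
#'
#' Generates \code{n_samples} independent degree-preserving randomizations
#' of the observed network (each a fresh swap chain from the original) and
#' evaluates each statistic on every sample.  The empirical p-value is the
#' fraction of samples at least as extreme as the observed value, in the
#' direction of the observed deviation from the null mean; when no sample
#' is as extreme the p-value is reported as the bound
#' \code{< 1/n_samples}.
#'
#' @param graph an igraph graph, \linkS4class{IIN} or
#'   \linkS4class{PPINetwork}.
#' @param statistics named list of functions, each a pure function of an
#'   igraph graph returning one number.
#' @param n_samples ensemble size (>= 2).
#' @param seed integer RNG seed (required).
#' @param n_accepted accepted swaps per sample (default 10 per swappable
#'   edge).
#' @return named list of \linkS4class{NullEnsemble} objects, one per
#'   statistic.
#' @examples
#' g <- igraph::sample_gnp(20, 0.25)
#' ens <- nullEnsemble(g, list(cl = function(x)
#'   clusteringCoefficients(x)$c_global), n_samples = 20, seed = 1)
#' ens$cl
#' @export
nullEnsemble <- function(graph, statistics, n_samples, seed,
                         n_accepted = NULL) {
  g <- asGraph(graph)
  if (missing(seed)) stop("an explicit `seed` is required")
  if (n_samples < 2L) stop("n_samples must be >= 2")
  if (is.null(names(statistics)) || any(!nzchar(names(statistics))))
    stop("statistics must be a named list of functions")
  observed <- vapply(statistics, function(f) as.numeric(f(g)), numeric(1))
  per <- matrix(NA_real_, n_samples, length(statistics),
                dimnames = list(NULL, names(statistics)))
  sample_seeds <- withSeed(seed,
    sample.int(.Machine$integer.max, n_samples))
  for (s in seq_len(n_samples)) {
    r <- maslovSneppen(g, n_accepted = n_accepted, seed = sample_seeds[s])
    per[s, ] <- vapply(statistics, function(f) as.numeric(f(r)), numeric(1))
  }
  out <- lapply(names(statistics), function(nm) {
    vals <- per[, nm]
    mu <- mean(vals); sdev <- stats::sd(vals)
    if (observed[nm] >= mu) {
      direction <- if (observed[nm] == mu) "equal" else "greater"
      exceed <- sum(vals >= observed[nm])
    } else {
      direction <- "less"
      exceed <- sum(vals <= observed[nm])
    }
    p_bound <- exceed == 0L
    p <- if (p_bound) 1 / n_samples else exceed / n_samples
    new("NullEnsemble", statistic = nm, observed = observed[[nm]],
        per_sample = as.numeric(vals), mean = mu, sd = sdev,
        exceed_count = as.integer(exceed), n_samples = as.integer(n_samples),
        p_value = p, p_bound = p_bound, direction = direction)
  })
  stats::setNames(out, names(statistics))
}
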