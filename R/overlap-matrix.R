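#' Consolidate an overlap matrix into interfaces
#'
#' Groups the partner-occurrences of a protein into binding interfaces:
#' two occurrences share an interface exactly when their matrix entry is 1,
#' so interfaces are the connected components of the entry==1 relation.
#' Interface indices are zero-based, assigned in order of first
#' partner-occurrence appearance in the matrix.
#'
#' A component that is not a clique is non-transitive: one surface overlaps
#' two others that do not overlap each other (as happens when a partner
#' binds across two distinct sites, and is resolved biologically by
#' splitting that partner's interface).  Automatic splitting would invent
#' interfaces, so under the default policy \code{"warn_merge"} the
#' component is kept whole and reported as a diagnostic naming an offending
#' occurrence triple; under \code{"error"} the matrix is rejected.
#'
#' @param matrix an \linkS4class{OverlapMatrix}.
#' @param policy \code{"warn_merge"} (default) or \code{"error"}.
#' @return A list with elements \code{interfaces} (data.frame with
#'   \code{index} and list column \code{members} of occurrence labels),
#'   \code{assignment} (named integer: interface index per occurrence
#'   label) and \code{diagnostics} (data.frame of non-transitive
#'   components: \code{index}, \code{triple}).
#' @examples
#' m <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' partitionInterfaces(OverlapMatrix("X", m))$interfaces
#' @export
partitionInterfaces <- function(matrix, policy = c("warn_merge", "error")) {
  policy <- match.arg(policy)
  stopifnot(is(matrix, "OverlapMatrix"))
  validObject(matrix)
  m <- matrix@entries
  labels <- rownames(m)
  k <- length(labels)
  ## connected components of the entry==1 relation, by label-order BFS so
  ## that indices follow first appearance
  comp <- rep(NA_integer_, k)
  nxt <- 0L
  for (i in seq_len(k)) {
    if (!is.na(comp[i])) next
    queue <- i
    comp[i] <- nxt
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(m[v, ] == 1L & is.na(comp))
      comp[nb] <- nxt
      queue <- c(queue, nb)
    }
    nxt <- nxt + 1L
  }
  ## non-transitivity: a component whose members are not mutually 1
  diags <- data.frame(index = integer(), triple = character(),
                      stringsAsFactors = FALSE)
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    if (length(idx) < 3L) next
    sub <- m[idx, idx, drop = FALSE]
    off <- sub[upper.tri(sub)]
    if (all(off == 1L)) next
    triple <- findOpenTriple(m, idx)
    msg <- sprintf(
      "interface %d of %s is non-transitive: %s and %s both overlap %s but not each other (resolve by splitting %s's interface)",
      cc, matrix@protein, triple[1], triple[2], triple[3], triple[3])
    if (policy == "error")
      stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    diags <- rbind(diags, data.frame(index = cc,
                                     triple = paste(triple, collapse = "|"),
                                     stringsAsFactors = FALSE))
  }
  members <- lapply(sort(unique(comp)), function(cc) labels[comp == cc])
  interfaces <- data.frame(index = sort(unique(comp)))
  interfaces$members <- members
  assignment <- stats::setNames(comp, labels)
  list(interfaces = interfaces, assignment = assignment, diagnostics = diags)
}

## first triple (a, b, c) in a component with a-c = 1, b-c = 1, a-b = 0;
## c is the occurrence whose interface spans the two others
findOpenTriple <- function(m, idx) {
  for (c_ in idx) {
    nb <- idx[which(m[c_, idx] == 1L)]
    if (length(nb) < 2L) next
    for (i in seq_len(length(nb) - 1L)) {
      for (j in (i + 1L):length(nb)) {
        if (m[nb[i], nb[j]] == 0L)
          return(c(rownames(m)[nb[i]], rownames(m)[nb[j]], rownames(m)[c_]))
      }
    }
  }
  stop("internal error: component flagged non-clique but no open triple found")
}
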