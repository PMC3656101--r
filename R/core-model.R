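#' Build an interface-interaction network from a PPI and overlap matrices
#'
#' Expands each assigned protein-protein edge into one interface-interface
#' edge per binding mode.  Every endpoint of an assigned edge must come
#' with an \linkS4class{OverlapMatrix} listing that partner once per mode,
#' and reciprocally: if A's matrix lists m occurrences of B, B's matrix
#' must list m occurrences of A under the same mode labels.  Each mode of
#' an edge A-B links the interface on A containing the B-occurrence of that
#' mode to the interface on B containing the matching A-occurrence; mode
#' pairing is by declared mode label, never positional.  A self
#' interaction with a single occurrence yields a self-loop on its
#' interface; with the two-surface occurrences (\code{@MODE.1},
#' \code{@MODE.2}) it yields an edge between two distinct interfaces of the
#' protein.  The resulting IIN has exactly sum(n_modes) edges over the
#' assigned PPI edges.
#'
#' @param ppi a \linkS4class{PPINetwork} (or an edge data.frame accepted by
#'   \code{\link{PPINetwork}}).
#' @param matrices list of \linkS4class{OverlapMatrix} objects, one per
#'   protein with assigned edges.
#' @param annotations optional list with elements \code{interfaces}
#'   (data.frame \code{protein}, \code{member} occurrence label,
#'   \code{domain_class}, optional \code{residues} list column) and
#'   \code{edges} (data.frame \code{a}, \code{b}, \code{mode},
#'   \code{evidence_grade}).  Unannotated interfaces get domain class
#'   \code{"other"}; unannotated edges get grade \code{"speculative"}.
#' @param policy non-transitivity policy passed to
#'   \code{\link{partitionInterfaces}}.
#' @return An \linkS4class{IIN}.
#' @examples
#' ppi <- PPINetwork(data.frame(a = "A", b = "B"))
#' mats <- list(OverlapMatrix("A", matrix(NA, 1, 1), labels = "B"),
#'              OverlapMatrix("B", matrix(NA, 1, 1), labels = "A"))
#' buildIIN(ppi, mats)
#' @export
buildIIN <- function(ppi, matrices, annotations = NULL,
                     policy = c("warn_merge", "error")) {
  policy <- match.arg(policy)
  if (!is(ppi, "PPINetwork")) ppi <- PPINetwork(ppi)
  validObject(ppi)
  mats <- list()
  for (m in matrices) {
    stopifnot(is(m, "OverlapMatrix"))
    if (m@protein %in% names(mats))
      stop("more than one overlap matrix for protein ", m@protein)
    mats[[m@protein]] <- m
  }
  edges <- ppi@edges
  assigned <- edges[edges$support_class %in% assignedClasses(), , drop = FALSE]

  ## modes declared for partner `q` in p's matrix: "mode" or "mode.slot"
  declaredModes <- function(p, q) {
    occ <- mats[[p]]@occurrences
    occ <- occ[occ$partner == q, , drop = FALSE]
    split(occ, occ$mode)
  }

  ## --- validate coverage, reciprocity, and occurrence provenance ---
  for (p in unique(c(assigned$a, assigned$b))) {
    if (is.null(mats[[p]]))
      stop("no overlap matrix for protein ", p,
           ", which has assigned interactions")
  }
  for (p in names(mats)) {
    occ <- mats[[p]]@occurrences
    if (!nrow(occ)) next
    partner_key <- pairKey(rep(p, nrow(occ)), occ$partner)
    known <- pairKey(assigned$a, assigned$b)
    bad <- !(partner_key %in% known)
    if (any(bad))
      stop("matrix for ", p, " lists occurrence(s) of ",
           paste(unique(occ$partner[bad]), collapse = ", "),
           " without an assigned PPI edge")
  }
  for (i in seq_len(nrow(assigned))) {
    a <- assigned$a[i]; b <- assigned$b[i]
    if (a == b) {
      by_mode <- declaredModes(a, a)
      if (length(by_mode) != assigned$n_modes[i])
        stop("self interaction ", a, ": matrix declares ", length(by_mode),
             " mode(s) but the PPI edge has n_modes = ", assigned$n_modes[i])
      for (mode in names(by_mode)) {
        slots <- sort(by_mode[[mode]]$slot)
        if (!identical(slots, 0L) && !identical(slots, c(1L, 2L)))
          stop("self interaction ", a, " mode ", mode,
               ": need one occurrence (shared surface) or slots .1 and .2",
               " (two surfaces)")
      }
    } else {
      ma <- declaredModes(a, b)
      mb <- declaredModes(b, a)
      if (length(ma) != length(mb) ||
          !setequal(names(ma), names(mb)))
        stop("reciprocity violation for ", a, "-", b, ": ", a, " declares ",
             length(ma), " occurrence(s) of ", b, " [",
             paste(names(ma), collapse = ","), "] but ", b, " declares ",
             length(mb), " of ", a, " [", paste(names(mb), collapse = ","),
             "]")
      if (length(ma) != assigned$n_modes[i])
        stop("edge ", a, "-", b, ": matrices declare ", length(ma),
             " mode(s) but the PPI edge has n_modes = ", assigned$n_modes[i])
      if (any(vapply(c(ma, mb), nrow, 1L) != 1L))
        stop("edge ", a, "-", b,
             ": repeated occurrences of one partner within a mode; label",
             " each binding mode explicitly as PARTNER@MODE")
    }
  }

  ## --- partition every matrix into interfaces ---
  parts <- lapply(mats, partitionInterfaces, policy = policy)

  ## --- node table ---
  node_rows <- list()
  for (p in names(mats)) {
    intf <- parts[[p]]$interfaces
    if (!nrow(intf)) next
    node_rows[[p]] <- data.frame(
      id = paste0(p, ".", intf$index), protein = p, index = intf$index,
      stringsAsFactors = FALSE)
    node_rows[[p]]$members <- intf$members
  }
  nodes <- do.call(rbind, node_rows)
  if (is.null(nodes))
    nodes <- data.frame(id = character(), protein = character(),
                        index = integer(), members = I(list()))
  rownames(nodes) <- NULL
  nodes$domain_class <- rep("other", nrow(nodes))
  nodes$residues <- rep(list(NULL), nrow(nodes))

  ## interface annotations, keyed by a member occurrence
  if (!is.null(annotations$interfaces) && nrow(nodes)) {
    ia <- annotations$interfaces
    for (j in seq_len(nrow(ia))) {
      hit <- which(nodes$protein == ia$protein[j] &
                   vapply(nodes$members,
                          function(mm) ia$member[j] %in% mm, logical(1)))
      if (!length(hit))
        stop("interface annotation refers to unknown occurrence ",
             ia$member[j], " of ", ia$protein[j])
      if (!ia$domain_class[j] %in% domainClasses())
        stop("unknown domain_class: ", ia$domain_class[j])
      nodes$domain_class[hit] <- ia$domain_class[j]
      if (!is.null(ia$residues)) nodes$residues[hit] <- ia$residues[j]
    }
  }

  ## occurrence label -> interface id
  nodeOf <- function(p, label) {
    paste0(p, ".", parts[[p]]$assignment[[label]])
  }

  ## edge grade lookup
  grade_key <- character(0)
  grade_val <- character(0)
  if (!is.null(annotations$edges)) {
    ea <- annotations$edges
    if (is.null(ea$mode)) ea$mode <- "1"
    if (!all(ea$evidence_grade %in% evidenceGrades()))
      stop("unknown evidence_grade token(s): ",
           paste(setdiff(ea$evidence_grade, evidenceGrades()), collapse = ", "))
    grade_key <- paste(pairKey(ea$a, ea$b), ea$mode)
    grade_val <- ea$evidence_grade
  }

  ## --- edge expansion: one IIN edge per binding mode ---
  us <- vs <- gr <- character(0)
  for (i in seq_len(nrow(assigned))) {
    a <- assigned$a[i]; b <- assigned$b[i]
    if (a == b) {
      by_mode <- declaredModes(a, a)
      for (mode in sort(names(by_mode))) {
        occ <- by_mode[[mode]]
        if (nrow(occ) == 1L) {
          u <- v <- nodeOf(a, occ$label)
        } else {
          occ <- occ[order(occ$slot), , drop = FALSE]
          u <- nodeOf(a, occ$label[1]); v <- nodeOf(a, occ$label[2])
        }
        us <- c(us, u); vs <- c(vs, v)
        gr <- c(gr, lookupGrade(grade_key, grade_val, pairKey(a, b), mode))
      }
    } else {
      ma <- declaredModes(a, b)
      for (mode in sort(names(ma))) {
        u <- nodeOf(a, ma[[mode]]$label)
        v <- nodeOf(b, declaredModes(b, a)[[mode]]$label)
        us <- c(us, u); vs <- c(vs, v)
        gr <- c(gr, lookupGrade(grade_key, grade_val, pairKey(a, b), mode))
      }
    }
  }
  iedges <- data.frame(u = us, v = vs, evidence_grade = gr,
                       stringsAsFactors = FALSE)
  dup <- duplicated(pairKey(iedges$u, iedges$v))
  if (any(dup))
    stop("distinct binding modes collapse onto the same interface pair ",
         pairKey(iedges$u, iedges$v)[dup][1],
         "; modes of one edge must engage distinct interfaces")
  new("IIN", nodes = nodes, edges = iedges, parent = ppi)
}

lookupGrade <- function(keys, vals, pk, mode) {
  hit <- match(paste(pk, mode), keys)
  if (is.na(hit)) "speculative" else vals[hit]
}

#' Project an IIN back onto its parent PPI
#'
#' Maps every interface-interface edge to its protein pair; the number of
#' binding modes of a pair is the multiplicity with which it appears.  The
#' result equals the assigned subset of the parent PPI exactly -- an IIN
#' uniquely defines its parent network.
#'
#' @param iin an \linkS4class{IIN}.
#' @return data.frame with columns \code{a}, \code{b}, \code{n_modes},
#'   sorted by protein pair.
#' @export
projectToPPI <- function(iin) {
  stopifnot(is(iin, "IIN"))
  validObject(iin)
  e <- iin@edges
  if (!nrow(e))
    return(data.frame(a = character(), b = character(), n_modes = integer(),
                      stringsAsFactors = FALSE))
  n <- iin@nodes
  pa <- n$protein[match(e$u, n$id)]
  pb <- n$protein[match(e$v, n$id)]
  a <- pmin(pa, pb); b <- pmax(pa, pb)
  key <- paste(a, b, sep = "--")
  tab <- table(key)
  parts <- strsplit(names(tab), "--", fixed = TRUE)
  out <- data.frame(a = vapply(parts, `[`, "", 1L),
                    b = vapply(parts, `[`, "", 2L),
                    n_modes = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Report the consequences of knocking out one interface
#'
#' Simulates the loss of a single binding interface (by mutation or a
#' surface-targeted inhibitor): lists the interface-interface edges removed
#' with the target, the remaining partners of each orphaned partner
#' interface, and whether the orphaned partner's protein can reroute --
#' i.e. whether any of that protein's interfaces still binds a partner
#' interface of the same domain class as the target (for instance, a
#' proline-rich interface that loses one SH3 domain but still reaches an
#' alternate SH3-bearing protein).
#'
#' @param iin an \linkS4class{IIN}.
#' @param target interface-node id to remove.
#' @return list with \code{target}, \code{target_domain_class},
#'   \code{removed_edges} (data.frame) and \code{orphans} (data.frame with
#'   \code{interface}, \code{protein}, \code{n_remaining},
#'   \code{remaining_partners} list column, and logical
#'   \code{alternate_route}).
#' @export
knockoutReport <- function(iin, target) {
  stopifnot(is(iin, "IIN"))
  n <- iin@nodes
  e <- iin@edges
  if (!target %in% n$id)
    stop("unknown interface node: ", target)
  tclass <- n$domain_class[match(target, n$id)]
  hit <- e$u == target | e$v == target
  removed <- e[hit, , drop = FALSE]
  kept <- e[!hit, , drop = FALSE]
  partner_ids <- unique(ifelse(removed$u == target, removed$v, removed$u))
  partner_ids <- setdiff(partner_ids, target)
  orphans <- data.frame(interface = partner_ids,
                        protein = n$protein[match(partner_ids, n$id)],
                        stringsAsFactors = FALSE)
  rem <- lapply(partner_ids, function(p)
    setdiff(unique(c(kept$v[kept$u == p], kept$u[kept$v == p])), character(0)))
  orphans$n_remaining <- vapply(rem, length, 1L)
  orphans$remaining_partners <- rem
  ## alternate route: some interface of the orphan's protein still binds a
  ## partner interface of the target's domain class
  orphans$alternate_route <- vapply(seq_along(partner_ids), function(i) {
    prot <- orphans$protein[i]
    own <- n$id[n$protein == prot]
    touching <- kept[kept$u %in% own | kept$v %in% own, , drop = FALSE]
    if (!nrow(touching)) return(FALSE)
    other <- ifelse(touching$u %in% own, touching$v, touching$u)
    any(n$domain_class[match(other, n$id)] == tclass)
  }, logical(1))
  list(target = target, target_domain_class = tclass,
       removed_edges = removed, orphans = orphans)
}

## igraph conversions ---------------------------------------------------------

#' @rdname asIgraph
#' @param support for a PPI network, support classes to keep (default: the
#'   assigned subset).
#' @export
setMethod("asIgraph", "PPINetwork", function(x, support = assignedClasses()) {
  e <- x@edges[x@edges$support_class %in% support, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    e[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = x@proteins$id,
                          membrane_binding = x@proteins$membrane_binding,
                          stringsAsFactors = FALSE))
  igraph::set_edge_attr(g, "support_class", value = e$support_class)
})

#' @rdname asIgraph
#' @export
setMethod("asIgraph", "IIN", function(x, ...) {
  g <- igraph::graph_from_data_frame(
    x@edges[, c("u", "v")], directed = FALSE,
    vertices = data.frame(name = x@nodes$id, protein = x@nodes$protein,
                          domain_class = x@nodes$domain_class,
                          stringsAsFactors = FALSE))
  igraph::set_edge_attr(g, "evidence_grade", value = x@edges$evidence_grade)
})

## normalize any supported input to an igraph graph
asGraph <- function(graph) {
  if (igraph::is_igraph(graph)) graph
  else if (is(graph, "IIN")) asIgraph(graph)
  else if (is(graph, "PPINetwork")) asIgraph(graph)
  else stop("expected an igraph graph, IIN or PPINetwork")
}
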