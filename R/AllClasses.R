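#' @import methods
NULL

## Controlled vocabularies ----------------------------------------------------

#' Controlled vocabularies for network annotation
#'
#' Enumerations used throughout the package: the support classes of curated
#' PPI edges (how well an interaction and its interfaces are backed by
#' experiment), the evidence grades of interface-interface edges, and the
#' interface domain classes that recur in endocytic networks.
#'
#' @return A character vector of allowed tokens.
#' @examples
#' supportClasses()
#' domainClasses()
#' @export
supportClasses <- function() {
  c("assigned", "assigned_added", "multi_study_unassigned",
    "single_ref_unassigned", "removed")
}

#' @rdname supportClasses
#' @export
evidenceGrades <- function() {
  c("crystal", "both_resolved", "both_resolved_in_vivo",
    "one_inferred", "both_inferred", "speculative")
}

#' @rdname supportClasses
#' @export
domainClasses <- function() {
  c("PRD", "SH3", "EH", "NPF", "phospho_site", "kinase",
    "clathrin_box", "acidic", "subunit_subunit", "membrane", "other")
}

## Support classes whose edges enter the IIN.
assignedClasses <- function() c("assigned", "assigned_added")

## PPINetwork -----------------------------------------------------------------

#' PPINetwork: a curated protein-protein interaction network
#'
#' Holds the protein table and the curated edge list of an undirected PPI
#' network.  Each unordered protein pair appears at most once; an edge
#' carries its support class, the number of distinct binding modes
#' (interface pairings) through which the pair interacts, and its literature
#' references.  Self-interactions (\code{a == b}) are allowed.  Edges of
#' every support class are retained in the data model, but only
#' \code{assigned}/\code{assigned_added} edges enter a derived
#' interface-interaction network.
#'
#' @slot proteins data.frame with columns \code{id}, \code{length},
#'   \code{membrane_binding}, \code{notes}.
#' @slot edges data.frame with columns \code{a}, \code{b},
#'   \code{support_class}, \code{n_modes}, \code{references}.
#' @export
setClass("PPINetwork",
         representation(proteins = "data.frame", edges = "data.frame"))

setValidity("PPINetwork", function(object) {
  p <- object@proteins
  e <- object@edges
  msgs <- character()
  need_p <- c("id", "length", "membrane_binding", "notes")
  need_e <- c("a", "b", "support_class", "n_modes", "references")
  if (!all(need_p %in% names(p)))
    return(paste("proteins must have columns:", paste(need_p, collapse = ", ")))
  if (!all(need_e %in% names(e)))
    return(paste("edges must have columns:", paste(need_e, collapse = ", ")))
  if (any(is.na(p$id)) || any(!nzchar(p$id)))
    msgs <- c(msgs, "protein ids must be nonempty")
  if (anyDuplicated(p$id))
    msgs <- c(msgs, "protein ids must be unique")
  if (any(!is.na(p$length) & p$length <= 0))
    msgs <- c(msgs, "protein lengths must be positive where given")
  if (nrow(e)) {
    if (!all(c(e$a, e$b) %in% p$id))
      msgs <- c(msgs, "edge endpoints must be listed proteins")
    if (!all(e$support_class %in% supportClasses()))
      msgs <- c(msgs, paste("unknown support_class token(s):",
                            paste(setdiff(e$support_class, supportClasses()),
                                  collapse = ", ")))
    if (any(e$n_modes < 1L) || any(e$n_modes != round(e$n_modes)))
      msgs <- c(msgs, "n_modes must be a positive integer")
    key <- pairKey(e$a, e$b)
    if (anyDuplicated(key))
      msgs <- c(msgs, paste("duplicate unordered protein pair(s):",
                            paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

## canonical key for an unordered pair
pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "--")
}

#' Construct a PPINetwork
#'
#' @param edges data.frame with columns \code{a}, \code{b} and optionally
#'   \code{support_class} (default \code{"assigned"}), \code{n_modes}
#'   (default 1) and \code{references} (default \code{""}).
#' @param proteins optional data.frame with column \code{id} and optionally
#'   \code{length}, \code{membrane_binding}, \code{notes}.  When omitted the
#'   protein table is derived from the edge endpoints.
#' @return A \linkS4class{PPINetwork}.
#' @examples
#' ppi <- PPINetwork(data.frame(a = "ACT1", b = "COF1"))
#' ppiEdges(ppi)
#' @export
PPINetwork <- function(edges, proteins = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(edges$support_class)) edges$support_class <- "assigned"
  if (is.null(edges$n_modes)) edges$n_modes <- 1L
  if (is.null(edges$references)) edges$references <- ""
  edges$n_modes <- as.integer(edges$n_modes)
  edges <- edges[c("a", "b", "support_class", "n_modes", "references")]
  if (is.null(proteins)) {
    proteins <- data.frame(id = sort(unique(c(edges$a, edges$b))),
                           stringsAsFactors = FALSE)
  } else {
    proteins <- as.data.frame(proteins, stringsAsFactors = FALSE)
  }
  if (is.null(proteins$length)) proteins$length <- NA_integer_
  if (is.null(proteins$membrane_binding)) proteins$membrane_binding <- FALSE
  if (is.null(proteins$notes)) proteins$notes <- ""
  proteins <- proteins[c("id", "length", "membrane_binding", "notes")]
  rownames(edges) <- NULL
  rownames(proteins) <- NULL
  new("PPINetwork", proteins = proteins, edges = edges)
}

## OverlapMatrix --------------------------------------------------------------

#' OverlapMatrix: per-protein interface overlap of binding partners
#'
#' For a protein with k partner-occurrences (a partner appears once per
#' binding mode), the symmetric k-by-k 0/1 matrix states, for every pair of
#' partner-occurrences, whether the two partners engage the same surface
#' (1) or separate surfaces (0).  Diagonal entries are undefined and stored
#' as \code{NA}.  A self-binding protein appears among its own partners,
#' either with a single occurrence (the same surface on both copies) or two
#' occurrences (two distinct surfaces).
#'
#' Occurrence labels follow the grammar \code{PARTNER},
#' \code{PARTNER@MODE} for explicit binding-mode labels, and
#' \code{PARTNER@MODE.1} / \code{PARTNER@MODE.2} for the two surfaces of a
#' two-surface self interaction.  A bare \code{PARTNER} label means mode
#' \code{"1"}; repeated occurrences of one partner must carry explicit mode
#' labels so that multi-mode pairings between two proteins' matrices are
#' never guessed positionally.
#'
#' @slot protein single protein id the matrix belongs to.
#' @slot occurrences data.frame with columns \code{label}, \code{partner},
#'   \code{mode}, \code{slot} (0 for ordinary occurrences, 1/2 for the two
#'   surfaces of a self pair).
#' @slot entries integer matrix (0/1 off the diagonal, \code{NA} on it) with
#'   occurrence labels as dimnames.
#' @export
setClass("OverlapMatrix",
         representation(protein = "character", occurrences = "data.frame",
                        entries = "matrix"))

setValidity("OverlapMatrix", function(object) {
  occ <- object@occurrences
  m <- object@entries
  msgs <- character()
  if (length(object@protein) != 1L || !nzchar(object@protein))
    msgs <- c(msgs, "protein must be a single nonempty id")
  if (nrow(m) != ncol(m))
    return("entries must be square")
  if (nrow(occ) != nrow(m))
    return("occurrence table and matrix dimension disagree")
  if (anyDuplicated(occ$label))
    msgs <- c(msgs, "occurrence labels must be unique")
  if (!identical(rownames(m), occ$label) || !identical(colnames(m), occ$label))
    msgs <- c(msgs, "matrix dimnames must equal the occurrence labels")
  if (nrow(m)) {
    off <- m[row(m) != col(m)]
    if (any(is.na(off)) || !all(off %in% c(0L, 1L)))
      msgs <- c(msgs, "off-diagonal entries must be 0 or 1")
    if (!is.null(asymm <- firstAsymmetry(m)))
      msgs <- c(msgs, paste0("entries not symmetric at (",
                             asymm[1], ", ", asymm[2], ")"))
    ## two occurrences of the same partner are distinct binding modes and so
    ## by definition use different surfaces
    for (p in unique(occ$partner[duplicated(occ$partner)])) {
      idx <- which(occ$partner == p)
      sub <- m[idx, idx, drop = FALSE]
      if (any(sub[row(sub) != col(sub)] == 1L))
        msgs <- c(msgs, paste0("occurrences of partner ", p,
                               " marked as sharing one surface"))
    }
  }
  if (length(msgs)) msgs else TRUE
})

## row/col labels of the first asymmetric cell, NULL if symmetric
firstAsymmetry <- function(m) {
  if (nrow(m) < 2L) return(NULL)
  for (i in seq_len(nrow(m) - 1L)) {
    for (j in (i + 1L):ncol(m)) {
      if (!identical(m[i, j], m[j, i]))
        return(c(rownames(m)[i], colnames(m)[j]))
    }
  }
  NULL
}

#' Parse partner-occurrence labels
#'
#' @param labels character vector of occurrence labels
#'   (\code{PARTNER}, \code{PARTNER@MODE}, \code{PARTNER@MODE.SLOT}).
#' @return data.frame with columns \code{label}, \code{partner},
#'   \code{mode}, \code{slot}.
#' @export
parseOccurrenceLabels <- function(labels) {
  if (any(!nzchar(labels)))
    stop("empty occurrence label")
  partner <- sub("@.*$", "", labels)
  rest <- ifelse(grepl("@", labels, fixed = TRUE),
                 sub("^[^@]*@", "", labels), "1")
  slot <- ifelse(grepl("\\.", rest), sub("^.*\\.", "", rest), "0")
  mode <- sub("\\..*$", "", rest)
  if (any(!nzchar(partner)) || any(!nzchar(mode)))
    stop("malformed occurrence label(s): ",
         paste(labels[!nzchar(partner) | !nzchar(mode)], collapse = ", "))
  if (!all(slot %in% c("0", "1", "2")))
    stop("self-surface slot must be .1 or .2")
  data.frame(label = labels, partner = partner, mode = mode,
             slot = as.integer(slot), stringsAsFactors = FALSE)
}

#' Construct an OverlapMatrix
#'
#' @param protein protein id the matrix describes.
#' @param entries square 0/1 matrix whose dimnames are partner-occurrence
#'   labels; the diagonal is ignored.  May also be given unnamed together
#'   with \code{labels}.
#' @param labels optional character vector of occurrence labels used when
#'   \code{entries} has no dimnames.
#' @return An \linkS4class{OverlapMatrix}.
#' @examples
#' m <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' OverlapMatrix("X", m)
#' @export
OverlapMatrix <- function(protein, entries, labels = NULL) {
  entries <- as.matrix(entries)
  if (!is.null(labels)) dimnames(entries) <- list(labels, labels)
  if (is.null(rownames(entries)))
    stop("occurrence labels required (dimnames or `labels`)")
  occ <- parseOccurrenceLabels(rownames(entries))
  storage.mode(entries) <- "integer"
  diag(entries) <- NA_integer_
  bare <- occ$mode == "1" & occ$slot == 0L & !grepl("@", occ$label, fixed = TRUE)
  dup <- occ$partner %in% occ$partner[duplicated(occ$partner)]
  if (any(bare & dup))
    stop("partner ", paste(unique(occ$partner[bare & dup]), collapse = ", "),
         " occurs more than once; label each occurrence explicitly as ",
         "PARTNER@MODE")
  key <- paste(occ$partner, occ$mode, occ$slot)
  if (anyDuplicated(key))
    stop("duplicate occurrence: ", key[duplicated(key)][1])
  new("OverlapMatrix", protein = protein, occurrences = occ, entries = entries)
}

## IIN ------------------------------------------------------------------------

#' IIN: an interface-interaction network
#'
#' Nodes are individual binding interfaces, named \code{PROTEIN.index} with
#' a zero-based index per protein; edges connect interfaces that bind one
#' another and carry an evidence grade.  An IIN projects uniquely onto its
#' parent PPI: mapping each edge to its protein pair and counting
#' multiplicities recovers the assigned subset of the parent network, and
#' the number of IIN edges equals the sum of \code{n_modes} over assigned
#' PPI edges.
#'
#' @slot nodes data.frame with columns \code{id}, \code{protein},
#'   \code{index}, \code{domain_class}, and list columns \code{members}
#'   (partner-occurrence labels grouped into the interface) and
#'   \code{residues}.
#' @slot edges data.frame with columns \code{u}, \code{v},
#'   \code{evidence_grade}.
#' @slot parent the \linkS4class{PPINetwork} the IIN was derived from.
#' @export
setClass("IIN",
         representation(nodes = "data.frame", edges = "data.frame",
                        parent = "PPINetwork"))

setValidity("IIN", function(object) {
  n <- object@nodes
  e <- object@edges
  msgs <- character()
  if (!all(c("id", "protein", "index", "domain_class") %in% names(n)))
    return("nodes must have columns id, protein, index, domain_class")
  if (!all(c("u", "v", "evidence_grade") %in% names(e)))
    return("edges must have columns u, v, evidence_grade")
  if (nrow(n)) {
    if (anyDuplicated(n$id))
      msgs <- c(msgs, "interface ids must be unique")
    if (!all(n$id == paste0(n$protein, ".", n$index)))
      msgs <- c(msgs, "interface ids must follow PROTEIN.index")
    if (anyDuplicated(paste(n$protein, n$index)))
      msgs <- c(msgs, "interface index must be unique within a protein")
    if (!all(n$domain_class %in% domainClasses()))
      msgs <- c(msgs, "unknown domain_class token(s)")
  }
  if (nrow(e)) {
    if (!all(c(e$u, e$v) %in% n$id))
      msgs <- c(msgs, "edge endpoints must be interface nodes")
    if (!all(e$evidence_grade %in% evidenceGrades()))
      msgs <- c(msgs, "unknown evidence_grade token(s)")
    if (anyDuplicated(pairKey(e$u, e$v)))
      msgs <- c(msgs, "duplicate interface pair(s)")
    ## every IIN edge must sit over a non-removed parent PPI edge
    pp <- object@parent@edges
    live <- pp[pp$support_class != "removed", , drop = FALSE]
    pu <- n$protein[match(e$u, n$id)]
    pv <- n$protein[match(e$v, n$id)]
    if (!all(pairKey(pu, pv) %in% pairKey(live$a, live$b)))
      msgs <- c(msgs, "IIN edge without a corresponding parent PPI edge")
  }
  if (length(msgs)) msgs else TRUE
})

## MotifCensus ----------------------------------------------------------------

#' Names of the six connected four-node motif classes
#'
#' \code{hub} and \code{chain} have 3 edges (star and path), \code{flag}
#' and \code{square} have 4 edges (triangle with a pendant edge, and the
#' chordless 4-cycle), and \code{diamond5} and \code{clique6} are the 5- and
#' 6-edge architectures.  The classes are mutually exclusive and exhaustive
#' over connected induced 4-node subgraphs.
#'
#' @return character vector of the six class names.
#' @export
motifClasses <- function() {
  c("hub", "chain", "flag", "square", "diamond5", "clique6")
}

#' MotifCensus: exact counts of connected four-node induced subgraphs
#'
#' @slot counts named integer vector over \code{\link{motifClasses}}.
#' @slot fractions counts normalized by \code{total} (all zero when
#'   \code{total} is 0).
#' @slot total number of connected 4-node subsets enumerated.
#' @export
setClass("MotifCensus",
         representation(counts = "integer", fractions = "numeric",
                        total = "integer"))

setValidity("MotifCensus", function(object) {
  if (!identical(names(object@counts), motifClasses()))
    return("counts must be named by the six motif classes")
  if (any(object@counts < 0L)) return("counts must be non-negative")
  if (sum(object@counts) != object@total)
    return("counts must sum to total")
  if (object@total > 0L && abs(sum(object@fractions) - 1) > 1e-9)
    return("fractions must sum to 1")
  TRUE
})

## PowerLawFit ----------------------------------------------------------------

#' PowerLawFit: a discrete power-law tail fit
#'
#' Maximum-likelihood fit of p(x) = x^-gamma / zeta(gamma, x_min) to the
#' integer sample values x >= x_min, with the Kolmogorov-Smirnov distance
#' between the tail empirical CDF and the fitted CDF, and (after a
#' bootstrap) a goodness-of-fit p-value.
#'
#' @slot x_min smallest value included in the tail.
#' @slot gamma exponent estimate.
#' @slot ks KS distance on the tail.
#' @slot p_value bootstrap goodness-of-fit p-value (\code{NA} before
#'   \code{\link{plGofPValue}} is run).
#' @slot n_tail number of samples with value >= x_min.
#' @slot degenerate TRUE when the tail carries no variation and the
#'   exponent ran to the optimization bound.
#' @export
setClass("PowerLawFit",
         representation(x_min = "integer", gamma = "numeric", ks = "numeric",
                        p_value = "numeric", n_tail = "integer",
                        degenerate = "logical"))

setValidity("PowerLawFit", function(object) {
  msgs <- character()
  if (object@x_min < 1L) msgs <- c(msgs, "x_min must be >= 1")
  if (!object@degenerate && object@gamma <= 1)
    msgs <- c(msgs, "gamma must exceed 1")
  if (object@ks < 0 || object@ks > 1) msgs <- c(msgs, "ks must lie in [0,1]")
  if (!is.na(object@p_value) && (object@p_value < 0 || object@p_value > 1))
    msgs <- c(msgs, "p_value must lie in [0,1]")
  if (object@n_tail < 2L) msgs <- c(msgs, "tail must hold >= 2 samples")
  if (length(msgs)) msgs else TRUE
})

## NullEnsemble ---------------------------------------------------------------

#' NullEnsemble: a statistic over degree-preserving randomized networks
#'
#' Summary of one graph statistic evaluated over an ensemble of
#' Maslov-Sneppen randomizations of an observed network, with the empirical
#' tail p-value for the observed value in the direction of its deviation
#' from the null mean.  When no randomized sample is as extreme as the
#' observation the p-value is reported as the bound \code{< 1/n_samples}
#' (slot \code{p_bound = TRUE}).
#'
#' @slot statistic name of the statistic.
#' @slot observed observed value on the input network.
#' @slot per_sample statistic values over the randomized samples.
#' @slot mean,sd ensemble summary.
#' @slot exceed_count number of samples at least as extreme as observed.
#' @slot n_samples ensemble size.
#' @slot p_value \code{exceed_count / n_samples} (or \code{1/n_samples}
#'   when \code{p_bound}).
#' @slot p_bound TRUE when the p-value is the zero-exceedance bound.
#' @slot direction \code{"less"}, \code{"greater"} or \code{"equal"}:
#'   side of the null mean the observation fell on.
#' @export
setClass("NullEnsemble",
         representation(statistic = "character", observed = "numeric",
                        per_sample = "numeric", mean = "numeric",
                        sd = "numeric", exceed_count = "integer",
                        n_samples = "integer", p_value = "numeric",
                        p_bound = "logical", direction = "character"))

setValidity("NullEnsemble", function(object) {
  msgs <- character()
  if (length(object@per_sample) != object@n_samples)
    msgs <- c(msgs, "per_sample length must equal n_samples")
  if (!is.na(object@sd) && object@sd < 0) msgs <- c(msgs, "sd must be >= 0")
  expected <- if (object@p_bound) 1 / object@n_samples else
    object@exceed_count / object@n_samples
  if (abs(object@p_value - expected) > 1e-12)
    msgs <- c(msgs, "p_value inconsistent with exceed_count/n_samples")
  if (length(msgs)) msgs else TRUE
})

## ContactInterface -----------------------------------------------------------

#' ContactInterface: an inter-chain interface from a structure
#'
#' Residue and heavy-atom contact sets between two chains of a multi-chain
#' structure at a stated distance cutoff.  An interface is valid only when
#' each side contributes at least three contacting residues.
#'
#' @slot chain_a,chain_b chain identifiers.
#' @slot residues_a,residues_b data.frames (\code{chain}, \code{resno},
#'   \code{insert}) of contacting residues on each side.
#' @slot atom_contacts data.frame of heavy-atom contact pairs
#'   (\code{eleno_a}, \code{eleno_b}, \code{resno_a}, \code{resno_b},
#'   \code{insert_a}, \code{insert_b}, \code{dist}).
#' @slot cutoff distance cutoff in Angstrom.
#' @export
setClass("ContactInterface",
         representation(chain_a = "character", chain_b = "character",
                        residues_a = "data.frame", residues_b = "data.frame",
                        atom_contacts = "data.frame", cutoff = "numeric"))
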