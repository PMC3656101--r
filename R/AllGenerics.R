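## Accessor generics and show methods.

#' Accessors for network objects
#'
#' \code{proteins} returns the protein table of a PPI network (or of an
#' IIN's parent); \code{ppiEdges} the curated PPI edge table;
#' \code{iinNodes}/\code{iinEdges} the interface node and edge tables of an
#' IIN; \code{parentPPI} the PPI an IIN was derived from;
#' \code{occurrences} and \code{overlapEntries} the occurrence table and
#' 0/1 matrix of an \linkS4class{OverlapMatrix}.
#'
#' @param x the object.
#' @return The corresponding table, matrix or object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))
#' @rdname accessors
#' @export
setGeneric("ppiEdges", function(x) standardGeneric("ppiEdges"))
#' @rdname accessors
#' @export
setGeneric("iinNodes", function(x) standardGeneric("iinNodes"))
#' @rdname accessors
#' @export
setGeneric("iinEdges", function(x) standardGeneric("iinEdges"))
#' @rdname accessors
#' @export
setGeneric("parentPPI", function(x) standardGeneric("parentPPI"))
#' @rdname accessors
#' @export
setGeneric("occurrences", function(x) standardGeneric("occurrences"))
#' @rdname accessors
#' @export
setGeneric("overlapEntries", function(x) standardGeneric("overlapEntries"))

#' Convert a network object to an igraph graph
#'
#' For a \linkS4class{PPINetwork} only edges of the requested support
#' classes are converted (by default the assigned subset that underlies a
#' derived IIN), with one edge per protein pair regardless of
#' \code{n_modes}.  For an \linkS4class{IIN} every interface-interface edge
#' becomes one graph edge; self-binding interfaces become self-loops.
#'
#' @param x a \linkS4class{PPINetwork} or \linkS4class{IIN}.
#' @param ... further arguments; for a PPI network, \code{support}, a
#'   character vector of support classes to keep.
#' @return an \code{igraph} graph with node/edge attributes.
#' @export
setGeneric("asIgraph", function(x, ...) standardGeneric("asIgraph"))

#' @rdname accessors
#' @export
setGeneric("motifCounts", function(x) standardGeneric("motifCounts"))
#' @rdname accessors
#' @export
setGeneric("motifFractions", function(x) standardGeneric("motifFractions"))

setMethod("proteins", "PPINetwork", function(x) x@proteins)
setMethod("proteins", "IIN", function(x) x@parent@proteins)
setMethod("ppiEdges", "PPINetwork", function(x) x@edges)
setMethod("iinNodes", "IIN", function(x) x@nodes)
setMethod("iinEdges", "IIN", function(x) x@edges)
setMethod("parentPPI", "IIN", function(x) x@parent)
setMethod("occurrences", "OverlapMatrix", function(x) x@occurrences)
setMethod("overlapEntries", "OverlapMatrix", function(x) x@entries)
setMethod("motifCounts", "MotifCensus", function(x) x@counts)
setMethod("motifFractions", "MotifCensus", function(x) x@fractions)

setMethod("show", "PPINetwork", function(object) {
  e <- object@edges
  cat("PPINetwork with", nrow(object@proteins), "proteins and",
      nrow(e), "interactions\n")
  if (nrow(e)) {
    tab <- table(factor(e$support_class, levels = supportClasses()))
    for (cl in names(tab)[tab > 0])
      cat("  ", cl, ": ", tab[[cl]], "\n", sep = "")
  }
})

setMethod("show", "OverlapMatrix", function(object) {
  cat("OverlapMatrix for ", object@protein, ": ",
      nrow(object@occurrences), " partner-occurrence(s), ",
      sum(object@entries[upper.tri(object@entries)] == 1L, na.rm = TRUE),
      " shared-surface pair(s)\n", sep = "")
})

setMethod("show", "IIN", function(object) {
  cat("IIN with", nrow(object@nodes), "interfaces on",
      length(unique(object@nodes$protein)), "proteins and",
      nrow(object@edges), "interface-interface edges\n")
})

setMethod("show", "MotifCensus", function(object) {
  cat("MotifCensus over", object@total, "connected 4-node subsets\n")
  print(data.frame(count = object@counts,
                   fraction = round(object@fractions, 4)))
})

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf("Discrete power-law fit: x_min = %d, gamma = %.3f, KS = %.4f, n_tail = %d\n",
              object@x_min, object@gamma, object@ks, object@n_tail))
  if (!is.na(object@p_value))
    cat(sprintf("  bootstrap goodness-of-fit p = %.3f\n", object@p_value))
  if (object@degenerate)
    cat("  (degenerate tail: no variation above x_min)\n")
})

setMethod("show", "NullEnsemble", function(object) {
  cat(sprintf("NullEnsemble '%s': observed %.4g, null %.4g +/- %.4g (n = %d)\n",
              object@statistic, object@observed, object@mean, object@sd,
              object@n_samples))
  cat(sprintf("  p %s%.4g (%s)\n", if (object@p_bound) "< " else "= ",
              object@p_value, object@direction))
})

setMethod("show", "ContactInterface", function(object) {
  cat(sprintf("ContactInterface %s-%s at %.1f A: %d/%d residues, %d atom contacts\n",
              object@chain_a, object@chain_b, object@cutoff,
              nrow(object@residues_a), nrow(object@residues_b),
              nrow(object@atom_contacts)))
})
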