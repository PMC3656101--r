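## Tab-separated file formats: edge lists (PPI and IIN), overlap matrices
## in the per-protein k-by-k layout with a "-" diagonal, SIF and GraphML
## exports.

#' Read a network edge list
#'
#' Tab-separated with a header row.  For \code{kind = "ppi"} the columns
#' are \code{protein_a}, \code{protein_b}, \code{support_class},
#' \code{n_modes}, \code{references} (semicolon-separated); the result is
#' a \linkS4class{PPINetwork}.  For \code{kind = "iin"} the columns are
#' \code{interface_a}, \code{interface_b}, \code{evidence_grade}, with
#' interface ids validated against the \code{PROTEIN.index} pattern; the
#' result is an igraph graph with an \code{evidence_grade} edge attribute
#' and a \code{protein} vertex attribute.  Duplicate unordered pairs and
#' unknown enum tokens are rejected with the offending line number.
#'
#' @param path file path.
#' @param kind \code{"ppi"} or \code{"iin"}.
#' @return A \linkS4class{PPINetwork} or an igraph graph.
#' @export
readNetworkTSV <- function(path, kind = c("ppi", "iin")) {
  kind <- match.arg(kind)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  lineOf <- function(i) i + 1L   # header is line 1
  if (kind == "ppi") {
    need <- c("protein_a", "protein_b", "support_class", "n_modes",
              "references")
    if (!all(need %in% names(tab)))
      stop(path, ": expected columns ", paste(need, collapse = ", "))
    bad <- which(!tab$support_class %in% supportClasses())
    if (length(bad))
      stop(path, " line ", lineOf(bad[1]), ": unknown support_class '",
           tab$support_class[bad[1]], "'")
    n_modes <- suppressWarnings(as.integer(tab$n_modes))
    bad <- which(is.na(n_modes) | n_modes < 1L)
    if (length(bad))
      stop(path, " line ", lineOf(bad[1]), ": invalid n_modes '",
           tab$n_modes[bad[1]], "'")
    dup <- which(duplicated(pairKey(tab$protein_a, tab$protein_b)))
    if (length(dup))
      stop(path, " line ", lineOf(dup[1]), ": duplicate edge ",
           tab$protein_a[dup[1]], "-", tab$protein_b[dup[1]])
    PPINetwork(data.frame(a = tab$protein_a, b = tab$protein_b,
                          support_class = tab$support_class,
                          n_modes = n_modes, references = tab$references,
                          stringsAsFactors = FALSE))
  } else {
    need <- c("interface_a", "interface_b", "evidence_grade")
    if (!all(need %in% names(tab)))
      stop(path, ": expected columns ", paste(need, collapse = ", "))
    ids <- c(tab$interface_a, tab$interface_b)
    bad <- which(!grepl("^.+\\.[0-9]+$", ids))
    if (length(bad))
      stop(path, ": invalid interface id '", ids[bad[1]],
           "' (expected PROTEIN.index)")
    bad <- which(!tab$evidence_grade %in% evidenceGrades())
    if (length(bad))
      stop(path, " line ", lineOf(bad[1]), ": unknown evidence_grade '",
           tab$evidence_grade[bad[1]], "'")
    dup <- which(duplicated(pairKey(tab$interface_a, tab$interface_b)))
    if (length(dup))
      stop(path, " line ", lineOf(dup[1]), ": duplicate edge ",
           tab$interface_a[dup[1]], "-", tab$interface_b[dup[1]])
    g <- igraph::graph_from_data_frame(
      tab[, c("interface_a", "interface_b")], directed = FALSE)
    igraph::V(g)$protein <- sub("\\.[0-9]+$", "", igraph::V(g)$name)
    igraph::set_edge_attr(g, "evidence_grade", value = tab$evidence_grade)
  }
}

#' Write a network edge list
#'
#' Inverse of \code{\link{readNetworkTSV}}: a \linkS4class{PPINetwork}
#' writes the ppi schema, an \linkS4class{IIN} the iin schema.
#'
#' @param network a \linkS4class{PPINetwork} or \linkS4class{IIN}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeNetworkTSV <- function(network, path) {
  if (is(network, "PPINetwork")) {
    e <- network@edges
    out <- data.frame(protein_a = e$a, protein_b = e$b,
                      support_class = e$support_class, n_modes = e$n_modes,
                      references = e$references, stringsAsFactors = FALSE)
  } else if (is(network, "IIN")) {
    e <- network@edges
    out <- data.frame(interface_a = e$u, interface_b = e$v,
                      evidence_grade = e$evidence_grade,
                      stringsAsFactors = FALSE)
  } else stop("network must be a PPINetwork or IIN")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-protein overlap matrix file
#'
#' The layout mirrors the per-protein bookkeeping files: a comment line
#' \code{#protein<TAB>NAME}, then a square tab-separated table whose first
#' row and first column hold the partner-occurrence labels, 0/1 cells, and
#' \code{"-"} on the diagonal.
#'
#' @param path file path.
#' @return An \linkS4class{OverlapMatrix}.
#' @export
readOverlapMatrixTSV <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^#protein\t", lines[1]))
    stop(path, ": first line must be '#protein<TAB>NAME'")
  protein <- sub("^#protein\t", "", lines[1])
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  header <- body[[1]][-1]
  k <- length(header)
  if (length(body) != k + 1L)
    stop(path, ": matrix is not square (", k, " columns, ",
         length(body) - 1L, " rows)")
  m <- matrix(NA_integer_, k, k, dimnames = list(header, header))
  for (i in seq_len(k)) {
    row <- body[[i + 1L]]
    if (length(row) != k + 1L)
      stop(path, ": row ", i, " has ", length(row) - 1L, " cells, expected ", k)
    if (row[1] != header[i])
      stop(path, ": row label '", row[1], "' does not match column label '",
           header[i], "'")
    vals <- row[-1]
    for (j in seq_len(k)) {
      if (i == j) {
        if (vals[j] != "-")
          stop(path, ": diagonal cell (", header[i], ") must be '-'")
      } else {
        if (!vals[j] %in% c("0", "1"))
          stop(path, ": cell (", header[i], ", ", header[j],
               ") must be 0 or 1, got '", vals[j], "'")
        m[i, j] <- as.integer(vals[j])
      }
    }
  }
  asym <- firstAsymmetry(m)
  if (!is.null(asym))
    stop(path, ": matrix not symmetric at (", asym[1], ", ", asym[2], ")")
  OverlapMatrix(protein, m)
}

#' @rdname readOverlapMatrixTSV
#' @param matrix an \linkS4class{OverlapMatrix} to write.
#' @export
writeOverlapMatrixTSV <- function(matrix, path) {
  stopifnot(is(matrix, "OverlapMatrix"))
  m <- matrix@entries
  labels <- rownames(m)
  cells <- apply(m, c(1, 2), function(v) if (is.na(v)) "-" else
    as.character(v))
  diag(cells) <- "-"
  lines <- c(paste0("#protein\t", matrix@protein),
             paste(c("", labels), collapse = "\t"),
             vapply(seq_along(labels), function(i)
               paste(c(labels[i], cells[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Export a network for graph viewers
#'
#' \code{exportSIF} writes the simple interaction format: one line per
#' edge, \code{source <type> target}, where the type token is the edge's
#' evidence grade (IIN) or support class (PPI); isolated nodes are written
#' as single-token lines.  \code{exportGraphML} writes GraphML with all
#' node and edge attributes via igraph.
#'
#' @param network a \linkS4class{PPINetwork}, \linkS4class{IIN} or igraph
#'   graph.
#' @param path output file path (for \code{exportSIF}, \code{NULL} returns
#'   the lines).
#' @return The SIF lines (invisibly when written to a file), or
#'   \code{path} for \code{exportGraphML}.
#' @export
exportSIF <- function(network, path = NULL) {
  g <- asGraph(network)
  el <- igraph::as_edgelist(g)
  type <- igraph::E(g)$evidence_grade
  if (is.null(type)) type <- igraph::E(g)$support_class
  if (is.null(type)) type <- rep("interacts", nrow(el))
  lines <- sprintf("%s\t%s\t%s", el[, 1], type, el[, 2])
  isolated <- igraph::V(g)$name[igraph::degree(g) == 0]
  lines <- c(lines, isolated)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @rdname exportSIF
#' @export
exportGraphML <- function(network, path) {
  g <- asGraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
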