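#' Write a toy multi-chain structure with designed contacts
#'
#' Emits a minimal valid PDB file in which chains are placed far apart
#' (so no accidental inter-chain contacts exist) and the requested
#' residue pairs are placed at exactly the requested heavy-atom distance.
#' Each residue carries two carbon atoms, CA and CB (1.5 Angstrom apart),
#' so interfaces can be designed to share residues with or without sharing
#' atoms.  Every contact directive moves the partner residue
#' (\code{chain_b}, \code{res_b}) next to the anchor atom
#' (\code{chain_a}, \code{res_a}, \code{atom_a}); successive directives on
#' one anchor atom fan out in different directions, so two partners
#' brought to the same anchor at, say, 3.8 Angstrom are more than 5
#' Angstrom from each other.
#'
#' @param chains named integer vector: residues per chain, e.g.
#'   \code{c(A = 10, B = 10)}.
#' @param contacts data.frame with columns \code{chain_a}, \code{res_a},
#'   \code{chain_b}, \code{res_b}, \code{dist} and optionally
#'   \code{atom_a} (\code{"CA"} default, or \code{"CB"}).  May be empty
#'   for a contact-free complex, but \code{chains} itself must be
#'   non-empty.
#' @param path optional file path; when given the PDB text is written
#'   there.
#' @return character vector of PDB lines (invisibly when \code{path} is
#'   given).
#' @examples
#' pdb <- toyStructurePDB(c(A = 6, B = 6),
#'   data.frame(chain_a = "A", res_a = 1:3, chain_b = "B", res_b = 1:3,
#'              dist = 3.8))
#' @export
toyStructurePDB <- function(chains, contacts = NULL, path = NULL) {
  if (is.null(names(chains)) || !length(chains) || any(!nzchar(names(chains))))
    stop("empty design: `chains` must be a named vector of residue counts")
  if (any(chains < 1)) stop("each chain needs at least one residue")
  if (is.null(contacts))
    contacts <- data.frame(chain_a = character(), res_a = integer(),
                           chain_b = character(), res_b = integer(),
                           dist = numeric(), stringsAsFactors = FALSE)
  contacts <- as.data.frame(contacts, stringsAsFactors = FALSE)
  if (nrow(contacts) && is.null(contacts$atom_a)) contacts$atom_a <- "CA"

  ## baseline: chain i on the line y = 100 i, residues 10 Angstrom apart
  pos <- list()   # pos[[chain]][[res]] = list(CA = xyz, CB = xyz)
  for (ci in seq_along(chains)) {
    ch <- names(chains)[ci]
    pos[[ch]] <- lapply(seq_len(chains[[ci]]), function(r) {
      ca <- c(10 * r, 100 * ci, 0)
      list(CA = ca, CB = ca + c(1.5, 0, 0))
    })
  }

  if (nrow(contacts)) {
    if (any(contacts$dist <= 0)) stop("contact distances must be positive")
    bad <- !(contacts$chain_a %in% names(chains)) |
      !(contacts$chain_b %in% names(chains))
    if (any(bad)) stop("contact directive names unknown chain")
    if (any(contacts$chain_a == contacts$chain_b))
      stop("contacts must be between different chains")
    if (any(contacts$res_a < 1 | contacts$res_a >
            chains[contacts$chain_a]) ||
        any(contacts$res_b < 1 | contacts$res_b > chains[contacts$chain_b]))
      stop("contact directive names unknown residue")
    moved <- paste(contacts$chain_b, contacts$res_b)
    if (anyDuplicated(moved))
      stop("contradictory distance directives: residue ",
           moved[duplicated(moved)][1], " is placed more than once")
    dirs <- list(c(0, 0, 1), c(0, 0, -1), c(0, 1, 0), c(0, -1, 0),
                 c(1, 0, 0), c(-1, 0, 0))
    anchor_use <- integer(0)
    for (k in seq_len(nrow(contacts))) {
      akey <- paste(contacts$chain_a[k], contacts$res_a[k],
                    contacts$atom_a[k])
      anchor_use[akey] <- if (is.na(anchor_use[akey])) 1L else
        anchor_use[[akey]] + 1L
      if (anchor_use[[akey]] > length(dirs))
        stop("too many partners on one anchor atom")
      d <- dirs[[anchor_use[[akey]]]]
      anchor <- pos[[contacts$chain_a[k]]][[contacts$res_a[k]]][[
        contacts$atom_a[k]]]
      ca <- anchor + d * contacts$dist[k]
      ## CB points away from the anchor so only CA makes the contact
      pos[[contacts$chain_b[k]]][[contacts$res_b[k]]] <-
        list(CA = ca, CB = ca + d * 1.5)
    }
  }

  lines <- character(0)
  serial <- 0L
  for (ch in names(chains)) {
    for (r in seq_len(chains[[ch]])) {
      for (at in c("CA", "CB")) {
        serial <- serial + 1L
        xyz <- pos[[ch]][[r]][[at]]
        lines <- c(lines, sprintf(
          "ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, sprintf(" %-3s", at), " ", "ALA", ch, r, " ",
          xyz[1], xyz[2], xyz[3], 1.00, 0.00, " C"))
      }
    }
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d", serial + 1L,
                              "ALA", ch, chains[[ch]]))
  }
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
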