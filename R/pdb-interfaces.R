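## Inter-chain contact interfaces from multi-chain structures.

.water_resids <- c("HOH", "WAT", "DOD", "H2O")

#' Read a structure file (PDB or mmCIF)
#'
#' PDB files go through \code{bio3d::read.pdb}; mmCIF files are read by a
#' minimal built-in \code{_atom_site} loop reader.  Only the first model is
#' kept.
#'
#' @param path path to a \code{.pdb}, \code{.ent}, \code{.cif} or
#'   \code{.mmcif} file.
#' @return data.frame of atoms with columns \code{type}, \code{eleno},
#'   \code{elety}, \code{elesy}, \code{alt}, \code{resid}, \code{chain},
#'   \code{resno}, \code{insert}, \code{x}, \code{y}, \code{z}, \code{o}.
#' @export
readStructure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
    return(readMmcifAtoms(path))
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file ", path,
                                           ": ", conditionMessage(e)))
  a <- pdb$atom
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1
  data.frame(type = a$type, eleno = a$eleno, elety = a$elety,
             elesy = toupper(trimws(ifelse(is.na(a$elesy), "", a$elesy))),
             alt = a$alt, resid = a$resid, chain = a$chain, resno = a$resno,
             insert = a$insert, x = a$x, y = a$y, z = a$z, o = a$o,
             stringsAsFactors = FALSE)
}

## minimal mmCIF _atom_site loop reader (first model only)
readMmcifAtoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  n <- length(lines)
  tags <- character()
  rows <- character()
  while (i <= n) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      j <- i + 1L
      t <- character()
      while (j <= n && grepl("^\\s*_", lines[j])) {
        t <- c(t, trimws(lines[j]))
        j <- j + 1L
      }
      if (length(t) && all(grepl("^_atom_site\\.", t))) {
        tags <- sub("^_atom_site\\.", "", t)
        while (j <= n && !grepl("^\\s*(#|loop_|_)", lines[j]) &&
               nzchar(trimws(lines[j]))) {
          rows <- c(rows, lines[j])
          j <- j + 1L
        }
        break
      }
      i <- j
    } else i <- i + 1L
  }
  if (!length(tags)) stop("no _atom_site loop found in ", path)
  toks <- strsplit(trimws(rows), "\\s+")
  bad <- vapply(toks, length, 1L) != length(tags)
  if (any(bad)) stop("malformed _atom_site row(s) in ", path)
  m <- do.call(rbind, toks)
  colnames(m) <- tags
  col <- function(name, default = NA_character_) {
    if (name %in% tags) m[, name] else rep(default, nrow(m))
  }
  dot <- function(v) ifelse(v %in% c(".", "?"), "", v)
  out <- data.frame(
    type = col("group_PDB", "ATOM"),
    eleno = as.integer(col("id")),
    elety = col("label_atom_id"),
    elesy = toupper(dot(col("type_symbol", ""))),
    alt = dot(col("label_alt_id", "")),
    resid = col("label_comp_id"),
    chain = ifelse(rep("auth_asym_id" %in% tags, nrow(m)),
                   col("auth_asym_id"), col("label_asym_id")),
    resno = as.integer(ifelse(rep("auth_seq_id" %in% tags, nrow(m)),
                              col("auth_seq_id"), col("label_seq_id"))),
    insert = dot(col("pdbx_PDB_ins_code", "")),
    x = as.numeric(col("Cartn_x")), y = as.numeric(col("Cartn_y")),
    z = as.numeric(col("Cartn_z")),
    o = suppressWarnings(as.numeric(dot(col("occupancy", "1")))),
    stringsAsFactors = FALSE)
  out$o[is.na(out$o)] <- 1
  model <- col("pdbx_PDB_model_num", "1")
  out[model == model[1], , drop = FALSE]
}

## normalize input to the atom data.frame of readStructure
structureAtoms <- function(structure) {
  if (is.character(structure) && length(structure) == 1L)
    return(readStructure(structure))
  if (inherits(structure, "pdb")) {
    tmp <- structure$atom
    tmp$insert[is.na(tmp$insert)] <- ""
    tmp$alt[is.na(tmp$alt)] <- ""
    tmp$o[is.na(tmp$o)] <- 1
    tmp$elesy <- toupper(trimws(ifelse(is.na(tmp$elesy), "", tmp$elesy)))
    return(tmp)
  }
  if (is.data.frame(structure)) return(structure)
  stop("structure must be a file path, a bio3d pdb object, or an atom table")
}

## polymer heavy atoms with highest-occupancy alternate locations:
## waters, ions and other non-polymer heteroatoms are excluded, but
## polymer-modified residues deposited as HETATM (e.g. selenomethionine)
## are retained
contactAtoms <- function(atoms) {
  keep <- atoms$type == "ATOM" |
    (atoms$type == "HETATM" &
       atoms$resid %in% c("MSE", "SEP", "TPO", "PTR", "CSO", "MLY", "HYP"))
  a <- atoms[keep & !(atoms$resid %in% .water_resids), , drop = FALSE]
  hyd <- a$elesy %in% c("H", "D") |
    (!nzchar(a$elesy) & grepl("^[0-9]*[HD]", a$elety))
  a <- a[!hyd, , drop = FALSE]
  ## alternate locations: keep the highest-occupancy one per atom site
  if (any(nzchar(a$alt) & a$alt != "A")) {
    site <- paste(a$chain, a$resno, a$insert, a$elety)
    ord <- order(site, -a$o)
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety)), ,
           drop = FALSE]
  } else {
    a <- a[!nzchar(a$alt) | a$alt == "A", , drop = FALSE]
  }
  a
}

## all index pairs (i in a, j in b) within `cutoff`, via a cell grid on b
closePairs <- function(xa, xb, cutoff) {
  keyb <- floor(xb / cutoff)
  kb <- paste(keyb[, 1], keyb[, 2], keyb[, 3])
  cells <- split(seq_len(nrow(xb)), kb)
  keya <- floor(xa / cutoff)
  res_i <- integer(0); res_j <- integer(0); res_d <- numeric(0)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(nrow(xa))) {
    keys <- sweep(off, 2, keya[i, ], `+`)
    cand <- unlist(cells[paste(keys[, 1], keys[, 2], keys[, 3])],
                   use.names = FALSE)
    if (!length(cand)) next
    d2 <- (xb[cand, 1] - xa[i, 1])^2 + (xb[cand, 2] - xa[i, 2])^2 +
      (xb[cand, 3] - xa[i, 3])^2
    hit <- d2 <= cutoff^2
    if (any(hit)) {
      res_i <- c(res_i, rep.int(i, sum(hit)))
      res_j <- c(res_j, cand[hit])
      res_d <- c(res_d, sqrt(d2[hit]))
    }
  }
  list(i = res_i, j = res_j, dist = res_d)
}

#' Extract inter-chain binding interfaces from a structure
#'
#' For every chain pair, finds heavy-atom pairs within the distance cutoff
#' (default 4 Angstrom between non-hydrogen atoms).  Waters, metal ions and
#' other non-polymer heteroatoms are excluded; polymer-modified residues
#' such as selenomethionine are retained.  Only the first model and the
#' highest-occupancy alternate locations are used.  An interface is kept
#' only if at least \code{min_residues} residues contact the partner on
#' each side (default 3).
#'
#' @param structure a file path, bio3d \code{pdb} object, or atom table
#'   from \code{\link{readStructure}}.
#' @param cutoff heavy-atom distance cutoff in Angstrom.
#' @param min_residues minimum contacting residues per side.
#' @return list of \linkS4class{ContactInterface} objects.
#' @export
extractInterfaces <- function(structure, cutoff = 4.0, min_residues = 3L) {
  if (cutoff <= 0) stop("cutoff must be positive")
  atoms <- contactAtoms(structureAtoms(structure))
  chains <- sort(unique(atoms$chain))
  if (length(chains) < 2L)
    stop("structure has fewer than 2 chains")
  by_chain <- split(seq_len(nrow(atoms)), atoms$chain)
  out <- list()
  for (ci in seq_len(length(chains) - 1L)) {
    for (cj in (ci + 1L):length(chains)) {
      ia <- by_chain[[chains[ci]]]
      ib <- by_chain[[chains[cj]]]
      xa <- as.matrix(atoms[ia, c("x", "y", "z")])
      xb <- as.matrix(atoms[ib, c("x", "y", "z")])
      ## bounding-box prefilter
      if (any(apply(xa, 2, min) - apply(xb, 2, max) > cutoff) ||
          any(apply(xb, 2, min) - apply(xa, 2, max) > cutoff)) next
      cp <- closePairs(xa, xb, cutoff)
      if (!length(cp$i)) next
      aa <- atoms[ia[cp$i], ]
      bb <- atoms[ib[cp$j], ]
      ra <- unique(data.frame(chain = aa$chain, resno = aa$resno,
                              insert = aa$insert, stringsAsFactors = FALSE))
      rb <- unique(data.frame(chain = bb$chain, resno = bb$resno,
                              insert = bb$insert, stringsAsFactors = FALSE))
      if (nrow(ra) < min_residues || nrow(rb) < min_residues) next
      contacts <- data.frame(eleno_a = aa$eleno, eleno_b = bb$eleno,
                             resno_a = aa$resno, resno_b = bb$resno,
                             insert_a = aa$insert, insert_b = bb$insert,
                             dist = cp$dist, stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <-
        new("ContactInterface", chain_a = chains[ci], chain_b = chains[cj],
            residues_a = ra, residues_b = rb, atom_contacts = contacts,
            cutoff = cutoff)
    }
  }
  out
}

#' Interface overlap table across a multi-protein complex
#'
#' The subunits of a complex bind simultaneously, so their pairwise
#' interfaces on a shared subunit measure how much residue (or atom)
#' overlap can occur without binding competition.  For each subunit S and
#' each unordered pair of S's interface partners, counts the interface
#' items of S (residues, or heavy atoms at \code{level = "atom"}) shared by
#' both interfaces, pools the pairs over all subunits, and reports the
#' fractions with 0, exactly 1, and more than 1 shared item as
#' percentages.
#'
#' @param structure a file path, bio3d \code{pdb} object, or atom table.
#' @param cutoff heavy-atom contact cutoff in Angstrom.
#' @param level \code{"residue"} or \code{"atom"}.
#' @param min_residues minimum contacting residues per interface side.
#' @return list with \code{level}, \code{cutoff}, \code{bins} (named
#'   percentages \code{zero}, \code{one}, \code{more}), \code{n_pairs} and
#'   \code{pairs} (per-pair detail: subunit, the two partners, shared item
#'   count).
#' @export
interfaceOverlapTable <- function(structure, cutoff = 4.0,
                                  level = c("residue", "atom"),
                                  min_residues = 3L) {
  level <- match.arg(level)
  ints <- extractInterfaces(structure, cutoff = cutoff,
                            min_residues = min_residues)
  if (!length(ints)) stop("no valid interfaces at cutoff ", cutoff)
  ## items of subunit `s` engaged in its interface with partner `p`
  itemsOn <- function(int, s) {
    a_side <- int@chain_a == s
    if (level == "residue") {
      r <- if (a_side) int@residues_a else int@residues_b
      paste(r$resno, r$insert)
    } else {
      if (a_side) unique(int@atom_contacts$eleno_a)
      else unique(int@atom_contacts$eleno_b)
    }
  }
  subunits <- sort(unique(unlist(lapply(ints, function(i)
    c(i@chain_a, i@chain_b)))))
  pairs <- data.frame(subunit = character(), partner_1 = character(),
                      partner_2 = character(), shared = integer(),
                      stringsAsFactors = FALSE)
  for (s in subunits) {
    mine <- Filter(function(i) i@chain_a == s || i@chain_b == s, ints)
    if (length(mine) < 2L) next
    partners <- vapply(mine, function(i)
      if (i@chain_a == s) i@chain_b else i@chain_a, character(1))
    for (p in seq_len(length(mine) - 1L)) {
      for (q in (p + 1L):length(mine)) {
        shared <- length(intersect(itemsOn(mine[[p]], s),
                                   itemsOn(mine[[q]], s)))
        pairs <- rbind(pairs, data.frame(
          subunit = s, partner_1 = partners[p], partner_2 = partners[q],
          shared = shared, stringsAsFactors = FALSE))
      }
    }
  }
  if (!nrow(pairs))
    stop("no subunit shares a common partner pair")
  bins <- c(zero = mean(pairs$shared == 0L),
            one = mean(pairs$shared == 1L),
            more = mean(pairs$shared > 1L)) * 100
  list(level = level, cutoff = cutoff, bins = bins,
       n_pairs = nrow(pairs), pairs = pairs)
}
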