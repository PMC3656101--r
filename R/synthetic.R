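#' Specification for the synthetic PPI/IIN generator
#'
#' Collects the knobs of \code{\link{generateGroundTruth}} with defaults
#' that emulate the curated yeast clathrin-mediated endocytosis (CME)
#' module: 56 proteins, a heavy-tailed PPI degree distribution with mean
#' degree about 6.4, a partner-sharing propensity calibrated so proteins
#' average about 3.5 distinct interfaces, and second/third binding modes at
#' the curated rates (16 double and 2 triple modes among 186 assigned
#' edges).  Unassigned and removed edges are added around the assigned
#' core at the curated proportions so derived networks must actively
#' exclude them.
#'
#' @param n_proteins number of proteins (>= 2).
#' @param degree_model \code{"powerlaw"} (degrees from a discrete power
#'   law with exponent \code{gamma} on \code{k >= k_min}, capped at
#'   \code{n_proteins - 1}) or \code{"poisson"} (Erdos-Renyi with the
#'   given \code{mean_degree}).
#' @param mean_degree target mean degree for the poisson model.
#' @param gamma,k_min power-law degree parameters.
#' @param sharing_propensity probability that a new partner-occurrence
#'   joins an existing interface rather than founding a new one.
#' @param sharing_mode how the joined interface is chosen among the
#'   eligible ones: \code{"preferential"} (probability proportional to
#'   current occupancy, producing the uneven splitting seen in real
#'   networks where one surface retains most of a hub protein's partners)
#'   or \code{"uniform"}.
#' @param multimode_prob probability an assigned edge carries a second
#'   binding mode.
#' @param trimode_frac fraction of multi-mode edges that carry a third
#'   mode.
#' @param selfloop_prob probability a protein self-interacts.
#' @param two_surface_prob probability a self interaction uses two
#'   distinct surfaces rather than the same surface on both copies.
#' @param unassigned_multi_frac,unassigned_single_frac,removed_frac extra
#'   non-assigned edges, as fractions of the assigned edge count.
#' @param seed integer RNG seed (required).
#' @return validated list of parameters with class \code{"SyntheticSpec"}.
#' @export
syntheticSpec <- function(n_proteins = 56,
                          degree_model = c("powerlaw", "poisson"),
                          mean_degree = 6.4, gamma = 3.2, k_min = 4,
                          sharing_propensity = 0.62,
                          sharing_mode = c("preferential", "uniform"),
                          multimode_prob = 18 / 186,
                          trimode_frac = 2 / 18,
                          selfloop_prob = 0.05,
                          two_surface_prob = 0.5,
                          unassigned_multi_frac = 28 / 186,
                          unassigned_single_frac = 145 / 186,
                          removed_frac = 35 / 186,
                          seed) {
  degree_model <- match.arg(degree_model)
  sharing_mode <- match.arg(sharing_mode)
  if (missing(seed)) stop("an explicit `seed` is required")
  probs <- c(sharing_propensity, multimode_prob, trimode_frac, selfloop_prob,
             two_surface_prob)
  if (any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (n_proteins < 2) stop("n_proteins must be >= 2")
  structure(list(n_proteins = as.integer(n_proteins),
                 degree_model = degree_model, mean_degree = mean_degree,
                 gamma = gamma, k_min = as.integer(k_min),
                 sharing_propensity = sharing_propensity,
                 sharing_mode = sharing_mode,
                 multimode_prob = multimode_prob, trimode_frac = trimode_frac,
                 selfloop_prob = selfloop_prob,
                 two_surface_prob = two_surface_prob,
                 unassigned_multi_frac = unassigned_multi_frac,
                 unassigned_single_frac = unassigned_single_frac,
                 removed_frac = removed_frac, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Generate a synthetic PPI with ground-truth interface assignments
#'
#' Samples an undirected PPI under the spec's degree model, then builds
#' each protein's interface partition by assigning its partner-occurrences
#' sequentially: an occurrence joins a uniformly chosen existing interface
#' with probability \code{sharing_propensity} (never one that already
#' holds another occurrence of the same partner -- distinct binding modes
#' engage distinct surfaces), else it founds a new interface.  Interfaces
#' are indexed in order of first occurrence.  The function emits mutually
#' consistent reciprocal overlap matrices, random domain-class and
#' evidence-grade annotations, and the exact IIN the assignments imply.
#' Output is bit-reproducible per seed.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return list with \code{ppi} (\linkS4class{PPINetwork}),
#'   \code{matrices} (list of \linkS4class{OverlapMatrix}),
#'   \code{annotations}, and \code{iin} (the ground-truth
#'   \linkS4class{IIN}).
#' @examples
#' gt <- generateGroundTruth(syntheticSpec(n_proteins = 12, seed = 1))
#' identical(iinEdges(buildIIN(gt$ppi, gt$matrices, gt$annotations)),
#'           iinEdges(gt$iin))
#' @export
generateGroundTruth <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  withSeed(spec$seed, {
    n <- spec$n_proteins
    prot <- sprintf("P%02d", seq_len(n))
    g <- samplePPIGraph(spec)
    el <- igraph::as_edgelist(g, names = FALSE)
    edges <- data.frame(a = prot[pmin(el[, 1], el[, 2])],
                        b = prot[pmax(el[, 1], el[, 2])],
                        stringsAsFactors = FALSE)
    ## self interactions
    self_on <- stats::runif(n) < spec$selfloop_prob
    if (any(self_on))
      edges <- rbind(edges, data.frame(a = prot[self_on], b = prot[self_on]))
    edges$support_class <- "assigned"
    edges$n_modes <- 1L
    multi <- edges$a != edges$b & stats::runif(nrow(edges)) < spec$multimode_prob
    edges$n_modes[multi] <- 2L
    tri <- multi & stats::runif(nrow(edges)) < spec$trimode_frac
    edges$n_modes[tri] <- 3L
    edges$references <- "synthetic"
    two_surface <- edges$a == edges$b &
      stats::runif(nrow(edges)) < spec$two_surface_prob

    ## surrounding unassigned/removed edges on pairs not already used
    n_assigned <- nrow(edges)
    extra_n <- c(multi_study_unassigned =
                   round(spec$unassigned_multi_frac * n_assigned),
                 single_ref_unassigned =
                   round(spec$unassigned_single_frac * n_assigned),
                 removed = round(spec$removed_frac * n_assigned))
    used <- pairKey(edges$a, edges$b)
    all_pairs <- t(utils::combn(prot, 2))
    free <- all_pairs[!pairKey(all_pairs[, 1], all_pairs[, 2]) %in% used, ,
                      drop = FALSE]
    take <- min(sum(extra_n), nrow(free))
    if (take > 0) {
      pick <- free[sample.int(nrow(free), take), , drop = FALSE]
      cls <- rep(names(extra_n), extra_n)[seq_len(take)]
      edges <- rbind(edges, data.frame(
        a = pick[, 1], b = pick[, 2], support_class = cls, n_modes = 1L,
        references = "synthetic", stringsAsFactors = FALSE))
    }
    ppi <- PPINetwork(edges,
                      proteins = data.frame(id = prot,
                                            stringsAsFactors = FALSE))

    ## occurrence lists per protein, in randomized arrival order
    assigned <- edges[edges$support_class == "assigned", , drop = FALSE]
    occ_of <- stats::setNames(
      rep(list(data.frame(partner = character(), mode = character(),
                          slot = integer(), stringsAsFactors = FALSE)), n),
      prot)
    addOcc <- function(p, partner, mode, slot) {
      occ_of[[p]] <<- rbind(occ_of[[p]],
                            data.frame(partner = partner, mode = mode,
                                       slot = slot, stringsAsFactors = FALSE))
    }
    for (i in seq_len(nrow(assigned))) {
      a <- assigned$a[i]; b <- assigned$b[i]; nm <- assigned$n_modes[i]
      if (a == b) {
        ## assigned rows are the leading rows of `edges`, so i indexes both
        if (two_surface[i]) {
          addOcc(a, a, "1", 1L); addOcc(a, a, "1", 2L)
        } else addOcc(a, a, "1", 0L)
      } else {
        for (m in seq_len(nm)) {
          addOcc(a, b, as.character(m), 0L)
          addOcc(b, a, as.character(m), 0L)
        }
      }
    }
    occ_of <- lapply(occ_of, function(occ) {
      if (nrow(occ) > 1L) occ[sample.int(nrow(occ)), , drop = FALSE] else occ
    })

    ## sequential interface assignment
    matrices <- list()
    assign_of <- list()
    for (p in prot) {
      occ <- occ_of[[p]]
      if (!nrow(occ)) next
      occ$label <- occLabel(occ)
      iface <- integer(nrow(occ))
      n_if <- 0L
      for (t in seq_len(nrow(occ))) {
        eligible <- if (n_if > 0L)
          setdiff(seq_len(n_if) - 1L,
                  unique(iface[seq_len(t - 1L)][occ$partner[seq_len(t - 1L)] ==
                                                  occ$partner[t]]))
        else integer(0)
        if (length(eligible) &&
            stats::runif(1) < spec$sharing_propensity) {
          w <- if (spec$sharing_mode == "preferential")
            vapply(eligible, function(e)
              sum(iface[seq_len(t - 1L)] == e), numeric(1))
          else rep(1, length(eligible))
          iface[t] <- eligible[sample.int(length(eligible), 1L, prob = w)]
        } else {
          iface[t] <- n_if
          n_if <- n_if + 1L
        }
      }
      m <- outer(iface, iface, `==`) * 1L
      storage.mode(m) <- "integer"
      diag(m) <- NA_integer_
      dimnames(m) <- list(occ$label, occ$label)
      matrices[[p]] <- new("OverlapMatrix", protein = p,
                           occurrences = parseOccurrenceLabels(occ$label),
                           entries = m)
      assign_of[[p]] <- stats::setNames(iface, occ$label)
    }

    ## annotations: a domain class per interface, a grade per edge mode
    node_rows <- list()
    ann_if <- list()
    for (p in names(matrices)) {
      iface <- assign_of[[p]]
      idx <- sort(unique(iface))
      members <- lapply(idx, function(ii) names(iface)[iface == ii])
      cls <- sample(domainClasses(), length(idx), replace = TRUE)
      node_rows[[p]] <- data.frame(id = paste0(p, ".", idx), protein = p,
                                   index = idx, stringsAsFactors = FALSE)
      node_rows[[p]]$members <- members
      node_rows[[p]]$domain_class <- cls
      ann_if[[p]] <- data.frame(
        protein = p,
        member = vapply(members, `[`, "", 1L),
        domain_class = cls, stringsAsFactors = FALSE)
    }
    nodes <- do.call(rbind, node_rows)
    rownames(nodes) <- NULL
    nodes$residues <- rep(list(NULL), nrow(nodes))
    nodes <- nodes[c("id", "protein", "index", "members", "domain_class",
                     "residues")]

    ## ground-truth IIN edges, in the same order buildIIN emits them
    us <- vs <- md <- as_ <- bs_ <- character(0)
    for (i in seq_len(nrow(assigned))) {
      a <- assigned$a[i]; b <- assigned$b[i]
      if (a == b) {
        occ <- matrices[[a]]@occurrences
        occ <- occ[occ$partner == a, , drop = FALSE]
        if (nrow(occ) == 2L) {
          occ <- occ[order(occ$slot), ]
          u <- paste0(a, ".", assign_of[[a]][[occ$label[1]]])
          v <- paste0(a, ".", assign_of[[a]][[occ$label[2]]])
        } else u <- v <- paste0(a, ".", assign_of[[a]][[occ$label[1]]])
        us <- c(us, u); vs <- c(vs, v); md <- c(md, "1")
        as_ <- c(as_, a); bs_ <- c(bs_, b)
      } else {
        for (m in sort(as.character(seq_len(assigned$n_modes[i])))) {
          la <- occLabelOne(b, m, assigned$n_modes[i])
          lb <- occLabelOne(a, m, assigned$n_modes[i])
          us <- c(us, paste0(a, ".", assign_of[[a]][[la]]))
          vs <- c(vs, paste0(b, ".", assign_of[[b]][[lb]]))
          md <- c(md, m); as_ <- c(as_, a); bs_ <- c(bs_, b)
        }
      }
    }
    grades <- sample(evidenceGrades(), length(us), replace = TRUE)
    ann_edges <- data.frame(a = as_, b = bs_, mode = md,
                            evidence_grade = grades, stringsAsFactors = FALSE)
    iedges <- data.frame(u = us, v = vs, evidence_grade = grades,
                         stringsAsFactors = FALSE)
    annotations <- list(interfaces = do.call(rbind, ann_if),
                        edges = ann_edges)
    iin_nodes <- nodes[c("id", "protein", "index", "members", "domain_class",
                         "residues")]
    iin <- new("IIN", nodes = iin_nodes, edges = iedges, parent = ppi)
    list(ppi = ppi, matrices = matrices, annotations = annotations,
         iin = iin)
  })
}

## label for one occurrence row: bare partner for single-mode, PARTNER@MODE
## for multi-mode, PARTNER@MODE.SLOT for two-surface self pairs
occLabel <- function(occ) {
  multi <- ave(seq_len(nrow(occ)), occ$partner,
               FUN = length) > 1L | occ$slot > 0L
  ifelse(occ$slot > 0L, paste0(occ$partner, "@", occ$mode, ".", occ$slot),
         ifelse(multi, paste0(occ$partner, "@", occ$mode), occ$partner))
}

occLabelOne <- function(partner, mode, n_modes) {
  if (n_modes > 1L) paste0(partner, "@", mode) else partner
}

## sample a simple undirected PPI graph per the spec's degree model,
## resampling infeasible degree sequences with capped retries
samplePPIGraph <- function(spec) {
  n <- spec$n_proteins
  if (spec$degree_model == "poisson") {
    p <- min(1, spec$mean_degree / (n - 1))
    return(igraph::sample_gnp(n, p))
  }
  for (try in seq_len(20L)) {
    deg <- samplePl(n, spec$gamma, spec$k_min)
    deg <- pmin(deg, n - 1L)
    if (sum(deg) %% 2L == 1L) deg[which.max(deg)] <- deg[which.max(deg)] - 1L
    if (igraph::is_graphical(deg)) {
      g <- tryCatch(suppressWarnings(igraph::sample_degseq(deg, method = "vl")),
                    error = function(e) NULL)
      if (!is.null(g)) return(g)
    }
    warning("degree sequence infeasible; resampling (attempt ", try, ")")
  }
  stop("could not realize a degree sequence after 20 attempts")
}
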