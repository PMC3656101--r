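test_that("all-distinct overlap matrix yields one interface per partner", {
  labs <- c("A", "B", "C")
  m <- matrix(0L, 3, 3, dimnames = list(labs, labs))
  res <- partitionInterfaces(OverlapMatrix("X", m))
  expect_equal(nrow(res$interfaces), 3L)
  expect_equal(res$interfaces$index, 0:2)
  expect_equal(unname(res$assignment), 0:2)
  expect_equal(nrow(res$diagnostics), 0L)
})

test_that("the ARC40 matrix consolidates into interfaces of sizes 6/1/1", {
  m <- readOverlapMatrixTSV(system.file("extdata", "ARC40_overlap.tsv",
                                        package = "iinet"))
  expect_equal(nrow(occurrences(m)), 8L)
  res <- partitionInterfaces(m)
  expect_equal(sort(lengths(res$interfaces$members)), c(1L, 1L, 6L))
  expect_equal(nrow(res$diagnostics), 0L)
  ## ARC19 and ARC15 use their own surfaces; the six co-overlapping
  ## partners share one
  shared <- res$interfaces$members[[which(lengths(res$interfaces$members) == 6)]]
  expect_setequal(shared, c("ACT1", "LAS17", "MYO5", "MYO3", "PAN1", "CRN1"))
})

test_that("non-transitive overlap components are flagged or rejected", {
  labs <- c("A", "B", "C")
  m <- matrix(0L, 3, 3, dimnames = list(labs, labs))
  m["A", "C"] <- m["C", "A"] <- 1L
  m["B", "C"] <- m["C", "B"] <- 1L
  om <- OverlapMatrix("X", m)
  expect_warning(res <- partitionInterfaces(om), "non-transitive")
  expect_equal(nrow(res$diagnostics), 1L)
  expect_match(res$diagnostics$triple, "C")     # C spans the two others
  expect_equal(nrow(res$interfaces), 1L)        # kept whole under warn_merge
  expect_error(partitionInterfaces(om, policy = "error"), "non-transitive")
})

test_that("non-transitivity detection agrees with the exhaustive clique oracle", {
  for (seed in 1:40) {
    set.seed(seed)
    k <- sample(3:12, 1)
    labs <- paste0("P", seq_len(k))
    m <- matrix(0L, k, k, dimnames = list(labs, labs))
    ones <- which(upper.tri(m) & matrix(runif(k * k) < 0.3, k, k))
    m[ones] <- 1L
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    om <- OverlapMatrix("X", m)
    comps <- oracleOverlapComponents(m)
    oracle_bad <- any(!vapply(comps, function(idx) oracleIsClique(m, idx),
                              logical(1)))
    res <- suppressWarnings(partitionInterfaces(om))
    expect_equal(nrow(res$diagnostics) > 0L, oracle_bad, info = seed)
    ## partition matches the oracle components regardless of cliqueness
    got <- lapply(res$interfaces$members, function(mm) sort(match(mm, labs)))
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(lapply(comps, sort), paste, collapse = ","))
  }
})

test_that("matrix validation rejects asymmetry and malformed labels", {
  labs <- c("A", "B")
  m <- matrix(c(NA, 1L, 0L, NA), 2, 2, dimnames = list(labs, labs))
  expect_error(OverlapMatrix("X", m), "symmetric")
  expect_error(OverlapMatrix("X", matrix(0L, 2, 2,
                                         dimnames = list(c("A", "A"),
                                                         c("A", "A")))),
               "explicitly")
})

test_that("a trivial one-edge network builds a two-node IIN", {
  ppi <- PPINetwork(data.frame(a = "A", b = "B"))
  mats <- list(OverlapMatrix("A", matrix(NA_integer_, 1, 1), labels = "B"),
               OverlapMatrix("B", matrix(NA_integer_, 1, 1), labels = "A"))
  iin <- buildIIN(ppi, mats)
  expect_equal(sort(iinNodes(iin)$id), c("A.0", "B.0"))
  expect_equal(nrow(iinEdges(iin)), 1L)
  expect_equal(iinEdges(iin)$evidence_grade, "speculative")
})

test_that("self interactions follow the one-entry/two-entry convention", {
  ## one occurrence: the same surface on both copies -> IIN self-loop
  ppi <- PPINetwork(data.frame(a = "S", b = "S"))
  m1 <- OverlapMatrix("S", matrix(NA_integer_, 1, 1), labels = "S")
  iin1 <- buildIIN(ppi, list(m1))
  expect_equal(iinEdges(iin1)$u, iinEdges(iin1)$v)
  expect_equal(nrow(iinNodes(iin1)), 1L)
  ## two occurrences: two distinct surfaces -> edge between two interfaces
  labs <- c("S@1.1", "S@1.2")
  m2 <- OverlapMatrix("S", matrix(c(NA, 0L, 0L, NA), 2, 2), labels = labs)
  iin2 <- buildIIN(ppi, list(m2))
  expect_equal(nrow(iinNodes(iin2)), 2L)
  e <- iinEdges(iin2)
  expect_false(e$u == e$v)
})

test_that("multi-mode edges pair by declared mode label", {
  ppi <- PPINetwork(data.frame(a = "A", b = "B", n_modes = 2))
  mA <- OverlapMatrix("A", matrix(c(NA, 0L, 0L, NA), 2, 2),
                      labels = c("B@1", "B@2"))
  mB <- OverlapMatrix("B", matrix(c(NA, 0L, 0L, NA), 2, 2),
                      labels = c("A@2", "A@1"))
  iin <- buildIIN(ppi, list(mA, mB))
  e <- iinEdges(iin)
  expect_equal(nrow(e), 2L)
  ## B@1 is A's first interface, and pairs with B's A@1 (B's second
  ## interface by label position): pairing follows labels, not positions
  expect_setequal(paste(e$u, e$v), c("A.0 B.1", "A.1 B.0"))
})

test_that("build validation catches missing matrices and reciprocity breaks", {
  ppi <- PPINetwork(data.frame(a = "A", b = "B"))
  mA <- OverlapMatrix("A", matrix(NA_integer_, 1, 1), labels = "B")
  expect_error(buildIIN(ppi, list(mA)), "no overlap matrix for protein B")
  mB2 <- OverlapMatrix("B", matrix(c(NA, 0L, 0L, NA), 2, 2),
                       labels = c("A@1", "A@2"))
  expect_error(buildIIN(ppi, list(mA, mB2)), "reciprocity")
  ## occurrence of a partner with no assigned edge
  mA2 <- OverlapMatrix("A", matrix(c(NA, 0L, 0L, NA), 2, 2),
                       labels = c("B", "Z"))
  ppi2 <- PPINetwork(data.frame(a = c("A", "A"), b = c("B", "Z"),
                                support_class = c("assigned", "removed")))
  mB <- OverlapMatrix("B", matrix(NA_integer_, 1, 1), labels = "A")
  expect_error(buildIIN(ppi2, list(mA2, mB)), "without an assigned PPI edge")
})

test_that("IIN edge count equals the sum of binding modes over assigned edges", {
  for (seed in c(3, 17, 44)) {
    gt <- generateGroundTruth(smallSpec(seed, n = 20))
    ae <- ppiEdges(gt$ppi)
    ae <- ae[ae$support_class %in% c("assigned", "assigned_added"), ]
    expect_equal(nrow(iinEdges(gt$iin)), sum(ae$n_modes))
  }
})

test_that("build/project round trip reproduces ground truth over 100 seeds", {
  for (seed in 1:100) {
    gt <- generateGroundTruth(smallSpec(seed))
    iin <- buildIIN(gt$ppi, gt$matrices, gt$annotations)
    expect_identical(iinEdges(iin), iinEdges(gt$iin), info = seed)
    expect_identical(iinNodes(iin), iinNodes(gt$iin), info = seed)
    proj <- projectToPPI(iin)
    ae <- ppiEdges(gt$ppi)
    ae <- ae[ae$support_class == "assigned", ]
    want <- data.frame(a = pmin(ae$a, ae$b), b = pmax(ae$a, ae$b),
                       n_modes = ae$n_modes, stringsAsFactors = FALSE)
    want <- want[order(want$a, want$b), ]
    rownames(want) <- NULL
    expect_identical(proj, want, info = seed)
  }
})

test_that("partitioning is a true partition of the partner occurrences", {
  for (seed in 1:20) {
    gt <- generateGroundTruth(smallSpec(seed))
    for (m in gt$matrices) {
      res <- partitionInterfaces(m)
      members <- unlist(res$interfaces$members)
      expect_setequal(members, occurrences(m)$label)
      expect_equal(length(members), nrow(occurrences(m)))
      expect_lte(nrow(res$interfaces), nrow(occurrences(m)))
    }
  }
})

test_that("projecting an empty IIN yields an empty edge list", {
  ppi <- PPINetwork(data.frame(a = "A", b = "B",
                               support_class = "single_ref_unassigned"))
  iin <- buildIIN(ppi, list())
  expect_equal(nrow(iinEdges(iin)), 0L)
  expect_equal(nrow(projectToPPI(iin)), 0L)
})

test_that("unassigned and removed edges never enter the IIN", {
  gt <- generateGroundTruth(smallSpec(7, n = 20))
  e <- ppiEdges(gt$ppi)
  expect_true(any(e$support_class != "assigned"))   # extras were generated
  proj <- projectToPPI(gt$iin)
  bad <- e[e$support_class %in% c("removed", "multi_study_unassigned",
                                  "single_ref_unassigned"), ]
  keyed <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_false(any(keyed(bad$a, bad$b) %in% keyed(proj$a, proj$b)))
})

test_that("knockout of a star hub orphans all partners with no alternates", {
  ppi <- PPINetwork(data.frame(a = "H", b = c("X", "Y", "Z")))
  mats <- c(list(OverlapMatrix("H", matrix(1L, 3, 3,
                                           dimnames = list(c("X", "Y", "Z"),
                                                           c("X", "Y", "Z"))))),
            lapply(c("X", "Y", "Z"), function(p)
              OverlapMatrix(p, matrix(NA_integer_, 1, 1), labels = "H")))
  iin <- buildIIN(ppi, mats)
  rep <- knockoutReport(iin, "H.0")
  expect_equal(nrow(rep$removed_edges), 3L)
  expect_equal(nrow(rep$orphans), 3L)
  expect_true(all(rep$orphans$n_remaining == 0L))
  expect_false(any(rep$orphans$alternate_route))
  expect_error(knockoutReport(iin, "H.9"), "unknown interface")
})

test_that("knockout flags alternate routes through same-class interfaces", {
  ## P binds SH3-class interfaces on X and Y; removing X leaves the Y route
  ppi <- PPINetwork(data.frame(a = "P", b = c("X", "Y")))
  mats <- list(OverlapMatrix("P", matrix(c(NA, 0L, 0L, NA), 2, 2,
                                         dimnames = list(c("X", "Y"),
                                                         c("X", "Y")))),
               OverlapMatrix("X", matrix(NA_integer_, 1, 1), labels = "P"),
               OverlapMatrix("Y", matrix(NA_integer_, 1, 1), labels = "P"))
  ann <- list(interfaces = data.frame(
    protein = c("P", "P", "X", "Y"), member = c("X", "Y", "P", "P"),
    domain_class = c("PRD", "PRD", "SH3", "SH3"), stringsAsFactors = FALSE))
  iin <- buildIIN(ppi, mats, ann)
  rep <- knockoutReport(iin, "X.0")
  expect_equal(rep$target_domain_class, "SH3")
  expect_equal(nrow(rep$orphans), 1L)
  expect_true(rep$orphans$alternate_route)
  ## and with Y reclassified as a kinase interface there is no alternate
  ann$interfaces$domain_class[4] <- "kinase"
  iin2 <- buildIIN(ppi, mats, ann)
  expect_false(knockoutReport(iin2, "X.0")$orphans$alternate_route)
})
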