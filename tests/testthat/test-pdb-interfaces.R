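test_that("designed contacts are recovered exactly at the 4 A cutoff", {
  path <- toyFile(c(A = 8, B = 8),
                  data.frame(chain_a = "A", res_a = 1:5, chain_b = "B",
                             res_b = 1:5, dist = 3.8))
  ints <- extractInterfaces(path, 4.0)
  expect_length(ints, 1L)
  expect_equal(residueNumbers(ints[[1]], "a"), 1:5)
  expect_equal(residueNumbers(ints[[1]], "b"), 1:5)
  expect_equal(ints[[1]]@cutoff, 4.0)
  ## every listed residue owns at least one atom contact
  expect_setequal(unique(ints[[1]]@atom_contacts$resno_a), 1:5)
})

test_that("contacts beyond the cutoff yield no interface", {
  path <- toyFile(c(A = 6, B = 6),
                  data.frame(chain_a = "A", res_a = 1:5, chain_b = "B",
                             res_b = 1:5, dist = 4.5))
  expect_length(extractInterfaces(path, 4.0), 0L)
  ## but a wider cutoff finds them
  expect_length(extractInterfaces(path, 5.0), 1L)
})

test_that("interfaces failing the 3-residue rule are discarded", {
  path <- toyFile(c(A = 6, B = 6),
                  data.frame(chain_a = "A", res_a = 1:2, chain_b = "B",
                             res_b = 1:2, dist = 3.8))
  expect_length(extractInterfaces(path, 4.0), 0L)
  expect_length(extractInterfaces(path, 4.0, min_residues = 2L), 1L)
})

test_that("extraction is symmetric and monotone in the cutoff", {
  path <- toyFile(c(A = 10, B = 10),
                  data.frame(chain_a = "A", res_a = 1:6, chain_b = "B",
                             res_b = 1:6, dist = c(3.2, 3.2, 3.2, 3.8, 3.8,
                                                   3.9)))
  i40 <- extractInterfaces(path, 4.0)[[1]]
  expect_equal(i40@chain_a, "A")   # symmetric storage: one record per pair
  expect_equal(nrow(i40@residues_a), 6L)
  i35 <- extractInterfaces(path, 3.5)[[1]]
  expect_equal(residueNumbers(i35, "a"), 1:3)
  expect_true(all(i35@residues_a$resno %in% i40@residues_a$resno))
  expect_true(all(i35@residues_b$resno %in% i40@residues_b$resno))
})

test_that("waters and ions near the interface are ignored", {
  path <- toyFile(c(A = 6, B = 6),
                  data.frame(chain_a = "A", res_a = 1:3, chain_b = "B",
                             res_b = 1:3, dist = 3.8))
  lines <- readLines(path)
  atoms <- readStructure(path)
  a1 <- atoms[atoms$chain == "A" & atoms$resno == 1 & atoms$elety == "CA", ]
  het <- c(sprintf(
    "HETATM%5d  O   HOH A %3d    %8.3f%8.3f%8.3f  1.00  0.00           O",
    900, 90, a1$x + 1.0, a1$y, a1$z),
    sprintf(
    "HETATM%5d ZN    ZN B %3d    %8.3f%8.3f%8.3f  1.00  0.00          ZN",
    901, 91, a1$x - 1.0, a1$y, a1$z))
  path2 <- tempfile(fileext = ".pdb")
  writeLines(c(lines[lines != "END"], het, "END"), path2)
  i1 <- extractInterfaces(path, 4.0)
  i2 <- extractInterfaces(path2, 4.0)
  expect_equal(length(i2), length(i1))
  expect_equal(residueNumbers(i2[[1]], "a"), residueNumbers(i1[[1]], "a"))
})

test_that("structures with fewer than two chains are rejected", {
  path <- toyFile(c(A = 5))
  expect_error(extractInterfaces(path, 4.0), "fewer than 2 chains")
  expect_error(extractInterfaces(path, -1), "positive")
})

test_that("disjoint faces give 100% zero-overlap pairs", {
  path <- toyFile(c(A = 6, B = 6, C = 12), rbind(
    data.frame(chain_a = "C", res_a = 1:3, chain_b = "A", res_b = 1:3,
               dist = 3.8),
    data.frame(chain_a = "C", res_a = 7:9, chain_b = "B", res_b = 1:3,
               dist = 3.8)))
  tab <- interfaceOverlapTable(path, 4.0, "residue")
  expect_equal(unname(tab$bins), c(100, 0, 0))
  expect_equal(tab$n_pairs, 1L)
})

test_that("a single shared residue lands in the exactly-one bin", {
  path <- toyFile(c(A = 6, B = 6, C = 12), rbind(
    data.frame(chain_a = "C", res_a = c(1, 2, 3), chain_b = "A", res_b = 1:3,
               dist = 3.8),
    data.frame(chain_a = "C", res_a = c(3, 4, 5), chain_b = "B", res_b = 1:3,
               dist = 3.8)))
  tab <- interfaceOverlapTable(path, 4.0, "residue")
  expect_equal(unname(tab$bins), c(0, 100, 0))
  expect_equal(tab$pairs$shared, 1L)
})

test_that("atom-level overlap refines residue-level overlap", {
  ## A touches residue 3 of C through its CA, B through its CB: the
  ## residue is shared but no atom is
  path <- toyFile(c(A = 6, B = 6, C = 12), rbind(
    data.frame(chain_a = "C", res_a = c(1, 2, 3), chain_b = "A", res_b = 1:3,
               dist = 3.8, atom_a = "CA"),
    data.frame(chain_a = "C", res_a = c(3, 4, 5), chain_b = "B", res_b = 1:3,
               dist = 3.8, atom_a = c("CB", "CA", "CA"))))
  res <- interfaceOverlapTable(path, 4.0, "residue")
  atm <- interfaceOverlapTable(path, 4.0, "atom")
  expect_equal(unname(res$bins), c(0, 100, 0))
  expect_equal(unname(atm$bins), c(100, 0, 0))
  ## refinement: the shared fraction cannot grow at atom level
  expect_lte(atm$bins[["one"]] + atm$bins[["more"]],
             res$bins[["one"]] + res$bins[["more"]])
})

test_that("the mmCIF reader reproduces the PDB-derived interfaces", {
  path <- toyFile(c(A = 8, B = 8),
                  data.frame(chain_a = "A", res_a = 1:4, chain_b = "B",
                             res_b = 1:4, dist = 3.6))
  atoms <- readStructure(path)
  cif <- tempfile(fileext = ".cif")
  writeMmcifFixture(atoms, cif)
  ip <- extractInterfaces(path, 4.0)
  ic <- extractInterfaces(cif, 4.0)
  expect_length(ic, length(ip))
  expect_equal(residueNumbers(ic[[1]], "a"), residueNumbers(ip[[1]], "a"))
  expect_equal(residueNumbers(ic[[1]], "b"), residueNumbers(ip[[1]], "b"))
  expect_error(readStructure(tempfile(fileext = ".cif")), "no such file")
})

test_that("alternate locations keep only the highest-occupancy copy", {
  path <- toyFile(c(A = 6, B = 6),
                  data.frame(chain_a = "A", res_a = 1:3, chain_b = "B",
                             res_b = 1:3, dist = 3.8))
  atoms <- readStructure(path)
  ## add a low-occupancy alternate B-side CA far from everything: it must
  ## not remove the contact, because the high-occupancy copy wins
  b1 <- atoms[atoms$chain == "B" & atoms$resno == 1 & atoms$elety == "CA", ]
  alt <- b1
  alt$alt <- "B"; alt$o <- 0.3; alt$x <- alt$x + 50
  atoms$alt[atoms$chain == "B" & atoms$resno == 1 &
              atoms$elety == "CA"] <- "A"
  atoms$o[atoms$chain == "B" & atoms$resno == 1 & atoms$elety == "CA"] <- 0.7
  cif <- tempfile(fileext = ".cif")
  writeMmcifFixture(rbind(atoms, alt), cif)
  ints <- extractInterfaces(cif, 4.0)
  expect_length(ints, 1L)
  expect_true(1 %in% ints[[1]]@residues_b$resno)
})
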