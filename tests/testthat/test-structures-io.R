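test_that("PDB parsing recovers atoms, elements and solvent flags", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "ATOM      2  H1  HOH A   1       0.957   0.000   0.000  1.00  0.00           H",
    "ATOM      3  H2  HOH A   1      -0.240   0.927   0.000  1.00  0.00           H",
    "END"), pdb)
  st <- readPDB(pdb)
  expect_equal(nAtoms(st), 3L)
  expect_equal(atomTable(st)$element, c("O", "H", "H"))
  expect_true(all(atomTable(st)$isSolvent))
})

test_that("malformed PDB coordinate lines are rejected with a line number", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  C   MOL A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  C   MOL A   1       bad     0.000   0.000  1.00  0.00           C"),
    pdb)
  expect_error(readPDB(pdb), "line 2")
})

test_that("PDB write/read round-trip preserves structure", {
  lc <- makeHostGuest(fixtureSpec(seed = 5), 1)
  st <- lc@complexStructure
  pdb <- tempfile(fileext = ".pdb")
  writePDB(st, pdb)
  back <- readPDB(pdb, perceive = FALSE)
  expect_equal(nAtoms(back), nAtoms(st))
  expect_equal(atomTable(back)$element, atomTable(st)$element)
  expect_equal(coords(back), coords(st), tolerance = 1e-3,
               ignore_attr = TRUE)
  canon <- function(b) {
    b <- cbind(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
    b[order(b[, 1], b[, 2]), , drop = FALSE]
  }
  expect_equal(canon(bondTable(back)), canon(bondTable(st)))
})

test_that("PQR parsing populates charges and radii in both dialects", {
  pqr <- tempfile(fileext = ".pqr")
  writeLines("ATOM 1 NA ION 1 0 0 0 1.000 1.868", pqr)
  st <- readPQR(pqr)
  expect_equal(nAtoms(st), 1L)
  expect_equal(atomTable(st)$charge, 1.0)
  expect_equal(atomTable(st)$radius, 1.868)
  expect_equal(atomTable(st)$element, "Na")

  ws <- tempfile(fileext = ".pqr")
  fx <- tempfile(fileext = ".pqr")
  writeLines(c("ATOM 1 C RES 1 1.5 0.25 -3.125 -0.60 1.70",
               "ATOM 2 O RES 1 2.5 0.25 -3.125 -0.70 1.50"), ws)
  writeLines(c(
    "ATOM      1  C   RES     1       1.500   0.250  -3.125 -0.6000 1.7000",
    "ATOM      2  O   RES     1       2.500   0.250  -3.125 -0.7000 1.5000"),
    fx)
  a <- readPQR(ws); b <- readPQR(fx)
  expect_equal(atomTable(a), atomTable(b))
  expect_equal(totalCharge(a), -1.3, tolerance = 1e-6)
})

test_that("PQR lines without charge/radius columns are a format error", {
  pqr <- tempfile(fileext = ".pqr")
  writeLines("ATOM 1 NA ION 1 0 0 0", pqr)
  expect_error(readPQR(pqr), "charge/radius")
})

test_that("parameter assignment fills unset values and falls back", {
  st <- mkStruct(c("O", "H", "H"),
                 c(0, 0.96, -0.24, 0, 0, 0.93, 0, 0, 0))
  st@atoms$radius <- NA_real_
  st@atoms$ljRminHalf <- NA_real_
  st@atoms$ljEpsilon <- NA_real_
  tab <- data.frame(element = c("O", "H"), radius = c(1.5, 1.2),
                    ljRminHalf = c(1.66, 0.6), ljEpsilon = c(0.21, 0.016))
  out <- assignParameters(st, tab)
  expect_equal(atomTable(out)$radius, c(1.5, 1.2, 1.2))

  # fully parameterized structure is unchanged by re-assignment
  again <- assignParameters(out, tab)
  expect_identical(atomTable(again), atomTable(out))

  # unknown element takes the carbon-like fallback with one warning
  st2 <- mkStruct("Xx", c(0, 0, 0))
  st2@atoms$radius <- NA_real_
  expect_warning(out2 <- assignParameters(st2, tab), "fallback")
  expect_equal(atomTable(out2)$radius, 1.70)

  expect_error(assignParameters(st, tab[0, ]), "empty")
})

test_that("solvent/ion stripping removes the blocklist and is idempotent", {
  solute <- mkStruct(rep("C", 10), cbind(seq_len(10) * 2, 0, 0),
                     charge = 0.1, resname = "MOL")
  waters <- mkStruct(rep(c("O", "H", "H"), 10),
                     cbind(seq_len(30) * 2 + 40, 5, 5), resname = "HOH")
  waters@atoms$isSolvent <- TRUE
  both <- methods::new("ParameterizedStructure",
                       atoms = rbind(solute@atoms, waters@atoms),
                       bonds = matrix(integer(0), ncol = 2),
                       role = "complex", name = "wet")
  dry <- stripSolventIons(both)
  expect_equal(nAtoms(dry), 10L)
  expect_identical(atomTable(stripSolventIons(dry)), atomTable(dry))

  withIon <- methods::new("ParameterizedStructure",
                          atoms = rbind(solute@atoms,
                                        mkStruct("Na", c(99, 0, 0),
                                                 charge = 1,
                                                 resname = "NA+")@atoms),
                          bonds = matrix(integer(0), ncol = 2),
                          role = "complex", name = "ion")
  noIon <- stripSolventIons(withIon)
  expect_equal(nAtoms(noIon), 10L)
  expect_equal(atomTable(noIon)$charge, rep(0.1, 10))
})

test_that("complex splitting partitions atoms and selectors agree", {
  n <- 100
  st <- mkStruct(rep("C", n), cbind(seq_len(n) * 1.6, 0, 0),
                 resname = c(rep("PRT", 80), rep("LIG", 20)))
  lcA <- splitComplex(st, "LIG")
  expect_equal(nAtoms(lcA@receptor), 80L)
  expect_equal(nAtoms(lcA@ligand), 20L)
  lcB <- splitComplex(st, 81:100)
  expect_equal(lcA@ligandIndices, lcB@ligandIndices)
  expect_equal(atomTable(lcA@ligand), atomTable(lcB@ligand))
  expect_true(methods::validObject(lcA))

  expect_error(splitComplex(st, "NOPE"), "no atoms")
  expect_error(splitComplex(st, seq_len(n)), "all atoms")
})

test_that("re-merged receptor and ligand reproduce the complex energies", {
  lc <- makeHostGuest(fixtureSpec(seed = 8, atomsPerHost = c(12L, 14L),
                                  atomsPerGuest = c(3L, 4L)), 1)
  # receptor atoms + ligand atoms re-assembled in complex order
  merged <- lc@complexStructure
  perm <- order(c(lc@receptorIndices, lc@ligandIndices))
  stacked <- rbind(atomTable(lc@receptor), atomTable(lc@ligand))[perm, ]
  rownames(stacked) <- NULL
  expect_equal(stacked, atomTable(merged))
  ebM <- energyBreakdown(merged)
  offs <- c(0L, nAtoms(lc@receptor))
  bonds <- rbind(bondTable(lc@receptor),
                 bondTable(lc@ligand) + nAtoms(lc@receptor))
  rebuilt <- methods::new("ParameterizedStructure", atoms = stacked,
                          bonds = {
                            m <- integer(nAtoms(merged))
                            m[perm] <- seq_along(perm)
                            idx <- c(lc@receptorIndices, lc@ligandIndices)
                            matrix(as.integer(idx[bonds]), ncol = 2)
                          },
                          role = "complex", name = "rebuilt")
  expect_equal(energyBreakdown(rebuilt), ebM, tolerance = 1e-9)
})
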