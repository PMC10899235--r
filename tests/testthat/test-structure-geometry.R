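test_that("structures round-trip through PDB and match the mmCIF rendering", {
  p <- bundle_pentamer()
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeStructurePDB(p, tmp)
  q <- readStructure(tmp)
  # PDB coordinates carry 3 decimals
  expect_equal(q$atom$x, p$atom$x, tolerance = 1e-3)
  expect_equal(q$atom$y, p$atom$y, tolerance = 1e-3)
  expect_equal(q$atom$z, p$atom$z, tolerance = 1e-3)
  expect_identical(q$atom$chain, p$atom$chain)
  expect_equal(q$atom$resno, as.integer(p$atom$resno))

  a <- readStructure(couplingExampleFile("pentamer_pdb"))
  b <- readStructure(couplingExampleFile("pentamer_cif"), format = "cif")
  expect_equal(as.numeric(a$xyz), as.numeric(b$xyz), tolerance = 1e-9)
  expect_identical(a$atom$chain, b$atom$chain)
  expect_identical(trimws(a$atom$elety), trimws(b$atom$elety))
})

test_that("only the first model and first altloc are kept on reading", {
  lines <- c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA AALA A   2       2.000   0.000   0.000  0.50  0.00           C",
    "ATOM      3  CA BALA A   2       9.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA  ALA A   3       3.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1      99.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  ALA A   3      99.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "END")
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, tmp)
  s <- readStructure(tmp)
  expect_identical(nrow(s$atom), 3L)        # model 1 only, altloc A kept
  expect_equal(sort(s$atom$x), c(1, 2, 3))
})

test_that("the estimated axis of a C5 bundle is the symmetry axis", {
  p <- bundle_pentamer()
  ax <- estimatePoreAxis(p)
  # angle to z below 1e-8 rad
  expect_lt(acos(min(abs(sum(ax@direction * c(0, 0, 1))), 1)), 1e-8)
  expect_equal(ax@anchor[1:2], c(0, 0), tolerance = 1e-9)
  expect_error(estimatePoreAxis(p, selection = 1:2), "3")
})

test_that("geometry is invariant under rigid-body transforms", {
  p <- bundle_pentamer()
  ax <- estimatePoreAxis(p)
  sel46 <- residueSelector("A", 46)
  sel265 <- residueSelector("A", 265)
  r46 <- radialDistance(p, ax, sel46)
  hb0 <- atomPairDistance(p, list(chain = "A", resno = 265, atom = "CB"),
                          list(chain = "B", resno = 46, atom = "CA"))
  col0 <- poreCollapseMetric(p, c("A", "C"))
  for (s in 1:5) {
    rot <- random_rotation(s)
    shift <- rnorm(3, 0, 20)
    q <- transformStructure(p, rot, shift)
    ax_q <- estimatePoreAxis(q)
    # axis co-rotates (up to sign)
    expect_equal(abs(sum(ax_q@direction * (rot %*% c(0, 0, 1)))), 1,
                 tolerance = 1e-8)
    expect_equal(radialDistance(q, ax_q, sel46), r46, tolerance = 1e-6)
    expect_equal(atomPairDistance(q, list(chain = "A", resno = 265,
                                          atom = "CB"),
                                  list(chain = "B", resno = 46, atom = "CA")),
                 hb0, tolerance = 1e-6)
    expect_equal(poreCollapseMetric(q, c("A", "C")), col0, tolerance = 1e-6)
    expect_identical(verdict(classifyRadialPosition(q, ax_q, sel46, sel265)),
                     "pore-distal")
  }
})

test_that("radial distances honour the aggregation rule and axis translation", {
  p <- buildSyntheticPentamer(data.frame(resno = 1, radius = 8, height = 5))
  ax <- poreAxis(anchor = c(0, 0, -40), direction = c(0, 0, 1))
  # CA at (8, 0, 5): perpendicular distance to the z-axis is the ring radius,
  # wherever the axis is anchored
  expect_equal(radialDistance(p, ax, residueSelector("A", 1, "CA")), 8,
               tolerance = 1e-12)
  expect_equal(radialDistance(p, ax, residueSelector("A", 1, "sidechain")), 8,
               tolerance = 1e-12)
  expect_equal(radialDistance(p, ax, residueSelector("A", 1, "atom",
                                                     atom = "CB")), 8,
               tolerance = 1e-12)
  expect_error(radialDistance(p, ax, residueSelector("Z", 1)), "Z")
  expect_error(radialDistance(p, ax, residueSelector("A", 1, "atom",
                                                     atom = "OG")), "OG")
})

test_that("radial classification applies the tie band and swap symmetry", {
  rings <- data.frame(resno = c(1, 2, 3), radius = c(5, 10, 10.1),
                      height = c(0, 0, 0))
  p <- buildSyntheticPentamer(rings)
  ax <- poreAxis()
  near <- residueSelector("A", 1); far <- residueSelector("A", 2)
  almost <- residueSelector("A", 3)
  expect_identical(verdict(classifyRadialPosition(p, ax, near, far)),
                   "pore-proximal")
  expect_identical(verdict(classifyRadialPosition(p, ax, far, near)),
                   "pore-distal")
  # |10.1 - 10| < 0.3: inside the tie band either way round
  expect_identical(verdict(classifyRadialPosition(p, ax, almost, far)),
                   "indeterminate")
  expect_identical(verdict(classifyRadialPosition(p, ax, far, almost)),
                   "indeterminate")
  expect_error(classifyRadialPosition(p, ax, near, near), "different")
})

test_that("an apo-like to bound-like ring shift flips the radial verdict", {
  # emulates the agonist-induced transition of the beta1-beta2 tip from the
  # pore-distal to the pore-proximal side of the M2-M3 proline
  apo <- bundle_pentamer(query_radius = 11)
  bound <- bundle_pentamer(query_radius = 5.5)
  for (ch in LETTERS[1:5]) {
    q <- residueSelector(ch, 46); ref <- residueSelector(ch, 265)
    expect_identical(
      verdict(classifyRadialPosition(apo, estimatePoreAxis(apo), q, ref)),
      "pore-distal")
    expect_identical(
      verdict(classifyRadialPosition(bound, estimatePoreAxis(bound), q, ref)),
      "pore-proximal")
  }
})

test_that("atom pair distances are Euclidean, symmetric and well-errored", {
  lines <- c(
    "ATOM      1  O   GLY G 182       0.000   0.000   0.000  1.00  0.00           O",
    "ATOM      2  N   SER A 268       3.000   4.000   0.000  1.00  0.00           N",
    "END")
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, tmp)
  s <- readStructure(tmp)
  o_spec <- list(chain = "G", resno = 182, atom = "O")
  n_spec <- list(chain = "A", resno = 268, atom = "N")
  expect_equal(atomPairDistance(s, o_spec, n_spec), 5)
  expect_equal(atomPairDistance(s, n_spec, o_spec), 5)
  expect_error(atomPairDistance(s, o_spec,
                                list(chain = "A", resno = 268, atom = "CA")),
               "CA")
})

test_that("the pore-collapse metric equals the closed-form chord length", {
  p <- bundle_pentamer()
  # chains A and C sit two azimuthal steps apart on the r = 6 A ring
  expect_equal(poreCollapseMetric(p, c("A", "C"), resno = 255),
               2 * 6 * sin(2 * pi / 5), tolerance = 1e-12)
  expect_error(poreCollapseMetric(p, c("A", "Z")), "Z")
})

test_that("side-chain centroids fall back to CA only for glycine-like residues", {
  lines <- c(
    "ATOM      1  N   SER A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  SER A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB  SER A   1       2.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  OG  SER A   1       4.000   0.000   0.000  1.00  0.00           O",
    "ATOM      5  N   GLY A   2       0.000   5.000   0.000  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2       1.000   5.000   0.000  1.00  0.00           C",
    "END")
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, tmp)
  s <- readStructure(tmp)
  ax <- poreAxis(direction = c(0, 1, 0))
  # SER: centroid of CB + OG = x = 3; GLY: CA fallback = x = 1
  expect_equal(radialDistance(s, ax, residueSelector("A", 1)), 3)
  expect_equal(radialDistance(s, ax, residueSelector("A", 2)), 1)
})
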