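test_that("residue templates have sane chemistry", {
  tpl <- residueTemplates()
  expect_true(all(c("GLY", "ALA", "SER", "VAL", "LEU", "PHE", "LYS",
                    "MET") %in% names(tpl)))
  for (nm in names(tpl)) {
    td <- tpl[[nm]]
    expect_true(all(c("N", "CA", "C", "O") %in% td$atom), label = nm)
    expect_true(all(td$element %in% c("C", "N", "O", "S")), label = nm)
    # bonded neighbors exist: every atom within 1.8 A of some other atom
    if (nrow(td) > 1) {
      xyz <- as.matrix(td[, c("x", "y", "z")])
      dd <- as.matrix(dist(xyz)); diag(dd) <- Inf
      expect_lt(max(apply(dd, 1, min)), 1.9)
    }
  }
  expect_equal(nrow(tpl$GLY), 4)
  expect_equal(nrow(tpl$ALA), 5)
})

test_that("generated helices have ideal CA geometry and a padded cell", {
  s <- generateStructure(10, seed = 4, cellPadding = 6)
  at <- atoms(s)
  ca <- at[at$atom == "CA", , drop = FALSE]
  expect_equal(nrow(ca), 10)
  d <- sqrt(rowSums(diff(as.matrix(ca[, c("x", "y", "z")]))^2))
  expect_true(all(abs(d - 3.8) < 0.5))
  # atoms respect the padding on every wall
  xyz <- as.matrix(at[, c("x", "y", "z")])
  cl <- unitCell(s)
  expect_true(all(xyz >= 6 - 1e-6))
  expect_true(all(sweep(xyz, 2, c(cl@a, cl@b, cl@c) - 6, "<=") | xyz < 6))
  expect_equal(min(xyz[, 1]), 6, tolerance = 1e-9)
  # explicit composition is used in order
  s2 <- generateStructure(3, composition = c("GLY", "ALA", "SER"), seed = 1)
  expect_equal(unique(atoms(s2)$resname[order(atoms(s2)$resno)]),
               c("GLY", "ALA", "SER"))
  # determinism
  expect_identical(atoms(generateStructure(6, seed = 11)),
                   atoms(generateStructure(6, seed = 11)))
  expect_false(identical(atoms(generateStructure(6, seed = 11)),
                         atoms(generateStructure(6, seed = 12))))
})

test_that("bundles pack clash-free parallel helices", {
  s <- generateBundle(8, nHelices = 3, helixSpacing = 9, seed = 2)
  at <- atoms(s)
  expect_setequal(unique(at$chain), c("A", "B", "C"))
  # no inter-chain clash below the placement threshold
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    a <- as.matrix(at[at$chain == pair[1], c("x", "y", "z")])
    b <- as.matrix(at[at$chain == pair[2], c("x", "y", "z")])
    expect_gte(min(BoxCC:::crossMinDist(a, b)), 2.4)
  }
  expect_error(generateBundle(8, nHelices = 8), "1..7")
  expect_error(generateBundle(8, nHelices = 3, helixSpacing = 1),
               "placement failure")
})

test_that("packEnvironment reaches the target density without clashes", {
  s <- generateBundle(8, nHelices = 3, helixSpacing = 9, seed = 2)
  ctr <- residueCentroid(residueAtoms(s, "A", 4))
  target <- 0.06
  p <- packEnvironment(s, ctr, edge = 10, targetDensity = target, seed = 5)
  at <- atoms(p)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  inBox <- colSums(abs(t(xyz) - ctr) <= 5) == 3
  expect_gte(sum(inBox), ceiling(target * 10^3))
  # filler is on its own chain and never clashes with the original atoms
  fil <- at$chain == "Z"
  expect_true(any(fil))
  expect_gte(min(BoxCC:::crossMinDist(xyz[fil, , drop = FALSE],
                                      xyz[!fil, , drop = FALSE])), 2.4)
  expect_identical(atoms(packEnvironment(s, ctr, edge = 10,
                                         targetDensity = target, seed = 5)),
                   at)
})

test_that("jitter RMSD matches the requested magnitude", {
  s <- generateStructure(20, seed = 6)
  for (mag in c(0.5, 1.5)) {
    p <- perturbStructure(s, perturbationSpec("jitter", mag, seed = 3))
    d <- as.matrix(atoms(p)[, c("x", "y", "z")]) -
      as.matrix(atoms(s)[, c("x", "y", "z")])
    rmsd <- sqrt(mean(rowSums(d^2)))
    expect_equal(rmsd, mag, tolerance = 0.15)
  }
  # magnitude 0 is the identity
  expect_identical(atoms(perturbStructure(s, perturbationSpec("jitter", 0))),
                   atoms(s))
})

test_that("sidechain rotation leaves the backbone fixed", {
  s <- generateStructure(8, composition = rep("LEU", 8), seed = 2)
  p <- perturbStructure(s, perturbationSpec("sidechain_rotate", 60,
                                            residues = 4L, seed = 1))
  a0 <- atoms(s); a1 <- atoms(p)
  moved <- abs(a1$x - a0$x) + abs(a1$y - a0$y) + abs(a1$z - a0$z) > 1e-9
  expect_true(any(moved))
  expect_true(all(a1$resno[moved] == 4))
  expect_false(any(a1$atom[moved] %in% c("N", "CA", "C", "O", "CB")))
  # bond lengths within the rotated sidechain are preserved
  rs <- a1$resno == 4
  d0 <- dist(as.matrix(a0[rs, c("x", "y", "z")]))
  d1 <- dist(as.matrix(a1[rs, c("x", "y", "z")]))
  expect_false(isTRUE(all.equal(as.numeric(d0), as.numeric(d1))))
})

test_that("segment shift and rigid body move by the stated amount", {
  s <- generateStructure(10, seed = 8)
  p <- perturbStructure(s, perturbationSpec("segment_shift", 2.0,
                                            residues = 3:5, seed = 2))
  d <- as.matrix(atoms(p)[, c("x", "y", "z")]) -
    as.matrix(atoms(s)[, c("x", "y", "z")])
  moved <- atoms(s)$resno %in% 3:5
  expect_equal(unname(sqrt(rowSums(d[moved, ]^2))),
               rep(2, sum(moved)), tolerance = 1e-9)
  expect_true(all(d[!moved, ] == 0))
  # determinism and seed sensitivity
  p2 <- perturbStructure(s, perturbationSpec("segment_shift", 2.0,
                                             residues = 3:5, seed = 2))
  expect_identical(atoms(p), atoms(p2))
  p3 <- perturbStructure(s, perturbationSpec("segment_shift", 2.0,
                                             residues = 3:5, seed = 3))
  expect_false(identical(atoms(p), atoms(p3)))
  expect_error(perturbStructure(s, perturbationSpec("jitter", 1,
                                                    residues = 99)),
               "empty residue range")
  expect_error(perturbationSpec("jitter", -1), ">= 0")
})

test_that("simulated maps lose contrast at worse resolution", {
  s <- generateStructure(8, seed = 3)
  m1 <- simulateObservedMap(s, 1.5, seed = 1)
  m3 <- simulateObservedMap(s, 3.0, seed = 1)
  # peak height over the same grid drops as resolution degrades
  expect_gt(max(mapValues(m1)), 1.5 * max(mapValues(m3)))
  # scoring against the model degrades too
  sc1 <- perResidueBcc(s, m1, spacing = 1.0)
  sc3 <- perResidueBcc(s, m3, spacing = 1.0)
  expect_gt(mean(sc1$bcc, na.rm = TRUE), mean(sc3$bcc, na.rm = TRUE))
  expect_error(simulateObservedMap(s, -1), "dMin")
})

test_that("ligand pockets sit 3.5-5 A from the pocket residue, clash-free", {
  s <- generateStructure(10, seed = 5, cellPadding = 12)
  b <- addLigandPocket(s, pocketResidue = 5, seed = 2)
  at <- atoms(b)
  lig <- at[at$resname == "LIG", , drop = FALSE]
  expect_equal(nrow(lig), 26)
  expect_true(all(lig$hetero))
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  prot <- at[!at$hetero, , drop = FALSE]
  pk <- as.matrix(prot[prot$resno == 5, c("x", "y", "z")])
  dmin <- min(BoxCC:::crossMinDist(lxyz, pk))
  expect_gte(dmin, 3.5)
  expect_lte(dmin, 5.0)
  expect_gte(min(BoxCC:::crossMinDist(lxyz,
                                      as.matrix(prot[, c("x", "y", "z")]))),
             2.2)
  # inside the cell
  cl <- unitCell(b)
  expect_true(all(lxyz > 0) && all(sweep(lxyz, 2, c(cl@a, cl@b, cl@c), "<")))
  expect_error(addLigandPocket(s, pocketResidue = 99), "not found")
  # tiny cell leaves no room
  tight <- generateStructure(10, seed = 5, cellPadding = 2)
  expect_error(addLigandPocket(tight, pocketResidue = 5, seed = 2),
               "placement failure")
})

test_that("generateTrainingCorpus writes a reproducible labeled archive", {
  cfg <- list(nStructures = 1, residuesPerStructure = 4,
              resolutions = c(2.0, 3.0), composition = c("ALA", "SER"),
              perturbations = list(list(mode = "jitter", magnitude = 1.0)),
              edge = 6, spacing = 1.0, seed = 42)
  p1 <- file.path(tempdir(), "corpus1")
  p2 <- file.path(tempdir(), "corpus2")
  arch <- generateTrainingCorpus(cfg, p1, overwrite = TRUE)
  # 1 structure x (1 correct + 1 perturbed) x 2 resolutions x 4 residues
  expect_equal(arch@manifest$nRecords, 16)
  expect_gt(arch@manifest$nLabeled, 0)
  expect_equal(arch@manifest$provenance$seed, 42)
  recs <- readRecords(arch)
  expect_length(recs, 16)
  expect_true(all(vapply(recs, function(r)
    identical(dim(r@channels), c(6L, 6L, 6L, 5L)), TRUE)))
  # correct variants score higher on average than the jittered ones
  v0 <- vapply(Filter(function(r) grepl("-v0$", r@meta$structureId), recs),
               function(r) r@label, numeric(1))
  v1 <- vapply(Filter(function(r) grepl("-v1$", r@meta$structureId), recs),
               function(r) r@label, numeric(1))
  expect_gt(mean(v0, na.rm = TRUE), mean(v1, na.rm = TRUE))
  # regeneration is bit-identical (same manifest hash)
  arch2 <- generateTrainingCorpus(cfg, p2, overwrite = TRUE)
  expect_identical(arch2@manifest$hash, arch@manifest$hash)
  expect_error(generateTrainingCorpus(list(nStructures = 1), p1),
               "lacks")
  unlink(c(p1, p2), recursive = TRUE)
})
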