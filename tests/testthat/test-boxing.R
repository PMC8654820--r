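test_that("residue centroid matches hand computation", {
  df <- rbind(atomRow("CA", "C", 0, 0, 0), atomRow("N", "N", 2, 0, 0),
              atomRow("O", "O", 0, 4, 0), atomRow("H", "H", 100, 100, 100))
  expect_equal(residueCentroid(df), c(2 / 3, 4 / 3, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  mw <- residueCentroid(df, massWeighted = TRUE)
  m <- c(12.011, 14.007, 15.999)
  expect_equal(as.numeric(mw),
               c(2 * m[2], 4 * m[3], 0) / sum(m), tolerance = 1e-12)
  expect_error(residueCentroid(df[4, , drop = FALSE]), "non-hydrogen")
})

test_that("cubeRotations is exactly the 24-element octahedral group", {
  rots <- cubeRotations()
  expect_length(rots, 24)
  expect_true(all(rots[[1]] == diag(3)))
  keys <- vapply(rots, function(m) paste(m, collapse = ","), "")
  expect_equal(length(unique(keys)), 24)
  # oracle: all signed permutation matrices with determinant +1
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  oracle <- character(0)
  for (p in perms) for (s1 in c(-1, 1)) for (s2 in c(-1, 1))
    for (s3 in c(-1, 1)) {
      m <- matrix(0L, 3, 3)
      sg <- c(s1, s2, s3)
      for (i in 1:3) m[i, p[i]] <- as.integer(sg[i])
      if (round(det(m)) == 1) oracle <- c(oracle, paste(m, collapse = ","))
    }
  expect_setequal(keys, oracle)
  # closure and orthogonality
  for (m in rots) {
    expect_equal(det(m), 1)
    expect_equal(t(m) %*% m, diag(3), ignore_attr = TRUE)
  }
})

test_that("rotateBox permutes voxels losslessly and composes correctly", {
  set.seed(42)
  arr <- array(rnorm(5^3), c(5, 5, 5))
  expect_identical(rotateBox(arr, 0), arr)
  for (k in 0:23) {
    r <- rotateBox(arr, k)
    expect_identical(sort(as.numeric(r)), sort(as.numeric(arr)))
  }
  # a rotation applied via the index map equals geometric coordinate remap
  rots <- cubeRotations()
  n <- 5
  for (k in c(1, 7, 15, 23)) {
    R <- rots[[k + 1]]
    r <- rotateBox(arr, k)
    # check a handful of voxels against the centered-coordinate oracle
    ctr <- (n + 1) / 2
    for (v in list(c(1, 1, 1), c(2, 4, 5), c(3, 3, 3), c(5, 1, 2))) {
      cin <- R %*% (v - ctr) + ctr      # voxel v maps to cin under R
      expect_equal(r[cin[1], cin[2], cin[3]], arr[v[1], v[2], v[3]])
    }
  }
  expect_error(rotateBox(arr, 24), "0..23")
  # VoxelBox in, VoxelBox out
  vb <- VoxelBox(arr, 2.5, 0.5, c(0, 0, 0), "test")
  rv <- rotateBox(vb, 3)
  expect_s4_class(rv, "VoxelBox")
  expect_identical(boxValues(rv), rotateBox(arr, 3))
})

test_that("trilinear box extraction is exact for affine fields", {
  # rho(x,y,z) = 2 + 3x - y + 0.5z is reproduced exactly by trilinear
  # interpolation; build it on a periodic grid large enough that the box
  # never crosses the wrap
  cl <- UnitCell(40, 40, 40)
  n <- 80
  g <- (0:(n - 1)) / n * 40
  f <- function(x, y, z) 2 + 3 * x - y + 0.5 * z
  arr <- array(0, c(n, n, n))
  for (k in seq_len(n)) arr[, , k] <- outer(g, g, function(x, y)
    f(x, y, g[k]))
  m <- DensityMap(arr, cl)
  ctr <- c(20.3, 19.7, 20.1)
  box <- extractBox(m, ctr, edge = 6, spacing = 0.5)
  off <- (0:11 - 5.5) * 0.5
  oracle <- array(0, c(12, 12, 12))
  for (k in 1:12) oracle[, , k] <- outer(ctr[1] + off, ctr[2] + off,
                                         function(x, y)
                                           f(x, y, ctr[3] + off[k]))
  expect_equal(boxValues(box), oracle, tolerance = 1e-9)
  expect_error(extractBox(m, ctr, edge = 5, spacing = 0.4), "multiple")
})

test_that("bcc equals brute-force Pearson and detects degeneracy", {
  set.seed(11)
  for (i in 1:5) {
    a <- array(rnorm(4^3), c(4, 4, 4))
    b <- array(rnorm(4^3) + 0.4 * as.numeric(a), c(4, 4, 4))
    av <- as.numeric(a); bv <- as.numeric(b)
    oracle <- sum((av - mean(av)) * (bv - mean(bv))) /
      sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
    expect_equal(bcc(a, b), oracle, tolerance = 1e-12)
  }
  a <- array(rnorm(27), c(3, 3, 3))
  expect_equal(bcc(a, a), 1, tolerance = 1e-12)
  expect_equal(bcc(a, -2 * a + 5), -1, tolerance = 1e-12)
  flat <- array(1, c(3, 3, 3))
  err <- tryCatch(bcc(a, flat), error = function(e) e)
  expect_s3_class(err, "degenerateBoxError")
  expect_error(bcc(a, array(0, c(2, 2, 2))), "differ in size")
})

test_that("bcc is invariant under a joint cube rotation", {
  set.seed(5)
  a <- array(rnorm(6^3), c(6, 6, 6))
  b <- array(rnorm(6^3) + 0.5 * as.numeric(a), c(6, 6, 6))
  base <- bcc(a, b)
  for (k in c(3, 10, 17)) {
    expect_equal(bcc(rotateBox(a, k), rotateBox(b, k)), base,
                 tolerance = 1e-12)
  }
})

test_that("per-residue bCC is near 1 on a self-consistent map", {
  fx <- selfConsistentFixture()
  sc <- perResidueBcc(fx$structure, fx$map)
  expect_gt(nrow(sc), 3)
  expect_true(all(is.na(sc$bcc) | sc$bcc >= 0.99))
  expect_true(all(sc$flag[!is.na(sc$bcc)] == ""))
})

test_that("single-atom contribution: outside-box atom warns and returns 0", {
  fx <- selfConsistentFixture()
  at <- atoms(fx$structure)
  # add a far-away water (distinct chain) and ask about it relative to
  # residue 1: clearly outside a 12 A box
  far <- atomRow("O", "O", at$x[1] + 30, at$y[1], at$z[1], chain = "W",
                 resno = 700L, resname = "HOH", hetero = TRUE)
  s <- fx$structure
  atoms(s) <- rbind(at, far)
  expect_warning(
    v <- singleAtomContribution(s, fx$map, chain = at$chain[1],
                                resno = at$resno[1],
                                atomSelector = list(chain = "W",
                                                    resno = 700L)),
    "outside")
  expect_equal(v, 0)
  expect_error(
    singleAtomContribution(s, fx$map, chain = at$chain[1],
                           resno = at$resno[1],
                           atomSelector = list(element = "C")),
    "exactly 1")
})
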