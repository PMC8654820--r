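test_that("synthesized maps conserve electron counts", {
  tab <- scatteringTable()
  cell <- UnitCell(14, 14, 14)
  for (el in c("C", "N", "O", "S")) {
    at <- atomRow(el, el, 7, 7, 7, b = 12)
    s <- XtalStructure(at, cell = cell, spaceGroup = "P 1")
    m <- synthesizeMap(s, c(28, 28, 28), table = tab)
    integral <- sum(mapValues(m)) * cellVolume(cell) / 28^3
    expect_equal(integral, electronCount(tab, el), tolerance = 0.01)
  }
})

test_that("F(000) equals the model electron count", {
  s <- dipeptideFixture()
  refl <- structureFactors(s, 1.2)
  rf <- reflections(refl)
  f0 <- rf$f[rf$h == 0 & rf$k == 0 & rf$l == 0]
  expect_equal(Re(f0), 6 + 7, tolerance = 0.01)
  expect_equal(Im(f0), 0, tolerance = 1e-9)
})

test_that("direct-sum and FFT maps agree on a dipeptide fixture", {
  s <- dipeptideFixture()
  refl <- structureFactors(s, 0.7)
  mf <- mapFromReflections(refl)
  md <- synthesizeMap(s, gridDims(mf))
  expect_gt(cor(as.numeric(mapValues(md)), as.numeric(mapValues(mf))),
            0.999)
})

test_that("Parseval identity holds between map and reflections", {
  s <- dipeptideFixture()
  dmin <- 1.0
  refl <- structureFactors(s, dmin)
  cell <- unitCell(s)
  # exact-Nyquist grid so the map holds exactly the enumerated frequencies
  m <- mapFromReflections(refl, dims = gridDimsForDmin(cell, dmin))
  v <- cellVolume(cell)
  n <- prod(gridDims(m))
  lhs <- sum(mapValues(m)^2) * v / n         # integral of rho^2
  rhs <- sum(Mod(reflections(refl)$f)^2) / v # sum |F|^2 / V
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("Friedel symmetry: F(-h) is the conjugate of F(h)", {
  s <- dipeptideFixture()
  rf <- reflections(structureFactors(s, 1.5))
  key <- paste(rf$h, rf$k, rf$l)
  mate <- match(paste(-rf$h, -rf$k, -rf$l), key)
  expect_false(anyNA(mate))
  expect_equal(rf$f, Conj(rf$f[mate]), tolerance = 1e-10)
})

test_that("resolution truncation keeps exactly the brute-force count", {
  s <- dipeptideFixture()
  refl <- structureFactors(s, 1.0)
  tr <- truncateResolution(refl, 2.0)
  # brute-force oracle on the original index list
  rf <- reflections(refl)
  q2 <- invResolutionSq(unitCell(s), cbind(rf$h, rf$k, rf$l))
  keep <- q2 <= 1 / 4 + 1e-12
  expect_equal(nrow(reflections(tr)), sum(keep))
  # surviving amplitudes are bitwise untouched
  rt <- reflections(tr)
  expect_identical(rt$f, rf$f[keep])
  expect_error(truncateResolution(tr, 1.0), "must be >=")
})

test_that("reflection noise is seeded, Friedel-safe, and scales", {
  s <- dipeptideFixture()
  refl <- structureFactors(s, 1.5)
  n1 <- addReflectionNoise(refl, 0.05, seed = 7)
  n2 <- addReflectionNoise(refl, 0.05, seed = 7)
  n3 <- addReflectionNoise(refl, 0.05, seed = 8)
  expect_identical(reflections(n1)$f, reflections(n2)$f)
  expect_false(identical(reflections(n1)$f, reflections(n3)$f))
  # Friedel symmetry survives
  rf <- reflections(n1)
  mate <- match(paste(-rf$h, -rf$k, -rf$l), paste(rf$h, rf$k, rf$l))
  expect_equal(rf$f, Conj(rf$f[mate]), tolerance = 1e-10)
  # F(000) untouched; noise magnitude grows with sigma
  f0 <- rf$h == 0 & rf$k == 0 & rf$l == 0
  expect_identical(rf$f[f0], reflections(refl)$f[f0])
  d1 <- mean(Mod(reflections(n1)$f - reflections(refl)$f)[!f0])
  d4 <- mean(Mod(reflections(addReflectionNoise(refl, 0.2, seed = 7))$f -
                   reflections(refl)$f)[!f0])
  expect_gt(d4, 2 * d1)
  # zero noise is the identity
  expect_identical(reflections(addReflectionNoise(refl, 0))$f,
                   reflections(refl)$f)
})

test_that("map synthesis rejects sub-Nyquist grids", {
  s <- dipeptideFixture()
  refl <- structureFactors(s, 1.0)
  expect_error(mapFromReflections(refl, dims = c(16, 16, 16)),
               "too coarse")
})

test_that("reflection text round trip preserves values", {
  s <- dipeptideFixture()
  refl <- structureFactors(s, 1.5)
  p <- tempfile(fileext = ".hkl")
  writeReflections(refl, p)
  back <- readReflections(p)
  expect_equal(reflections(back)$f, reflections(refl)$f, tolerance = 1e-9)
  expect_equal(dMin(back), dMin(refl))
  unlink(p)
})
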