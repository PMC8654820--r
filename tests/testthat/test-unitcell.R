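test_that("orthogonalization round-trips and volume matches oracle", {
  cl <- UnitCell(20, 30, 40, 90, 100, 95)
  # oracle: V = abc sqrt(1 - cos^2 - cos^2 - cos^2 + 2 cos cos cos)
  ca <- cos(90 * pi / 180); cb <- cos(100 * pi / 180)
  cg <- cos(95 * pi / 180)
  vOracle <- 20 * 30 * 40 *
    sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  expect_equal(cellVolume(cl), vOracle, tolerance = 1e-12)
  expect_equal(det(orthMatrix(cl)), vOracle, tolerance = 1e-10)
  xyz <- matrix(c(1.5, 2.5, 3.5, -4, 50, 7), 2, 3, byrow = TRUE)
  expect_equal(orthogonalize(cl, fractionalize(cl, xyz)), xyz,
               tolerance = 1e-10)
  expect_equal(fracMatrix(cl) %*% orthMatrix(cl), diag(3),
               tolerance = 1e-10)
})

test_that("orthorhombic cells give diagonal matrices", {
  cl <- UnitCell(10, 20, 30)
  expect_equal(orthMatrix(cl), diag(c(10, 20, 30)), tolerance = 1e-12)
})

test_that("invalid cell parameters are rejected", {
  expect_error(UnitCell(-5, 10, 10), "positive|valid")
  expect_error(UnitCell(10, 10, 10, alpha = 0), "angle|valid")
  expect_error(UnitCell(10, 10, 10, alpha = 180), "angle|valid")
})

test_that("inverse resolution matches the orthorhombic oracle", {
  cl <- UnitCell(10, 20, 40)
  hkl <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(2, 3, 4))
  oracle <- (hkl[, 1] / 10)^2 + (hkl[, 2] / 20)^2 + (hkl[, 3] / 40)^2
  expect_equal(invResolutionSq(cl, hkl), oracle, tolerance = 1e-12)
})
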