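test_that("atomic density integrates to the electron number", {
  tab <- scatteringTable()
  # quadrature oracle: 4 pi int r^2 rho(r) dr over a generous radius
  for (el in c("C", "N", "O", "S")) {
    f <- function(r) 4 * pi * r^2 * atomicDensity(el, r, bIso = 15,
                                                  table = tab)
    z <- integrate(f, 0, 12, rel.tol = 1e-10)$value
    expect_equal(z, electronCount(tab, el), tolerance = 5e-3)
  }
})

test_that("peak density matches the termwise oracle", {
  tab <- scatteringTable()
  i <- match("C", tab@elements)
  a <- tab@a[, i]; b <- tab@b[, i]
  B <- 7.5
  oracle <- sum(a * (4 * pi / (B + b))^1.5)
  expect_equal(atomicDensity("C", 0, bIso = B, table = tab), oracle,
               tolerance = 1e-12)
})

test_that("density is positive and decreasing despite the folded constant", {
  tab <- scatteringTable()
  r <- seq(0, 4, by = 0.01)
  for (el in tab@elements) {
    for (B in c(0.5, 2, 30)) {
      rho <- atomicDensity(el, r, bIso = B, table = tab)
      expect_true(all(rho > 0), label = paste(el, B, "positive"))
      expect_true(all(diff(rho) < 0), label = paste(el, B, "monotone"))
    }
  }
})

test_that("non-positive effective width is rejected", {
  tab <- scatteringTable()
  expect_error(atomicDensity("C", 1, bIso = 0, table = tab), "B_iso")
  expect_error(atomicDensity("C", 1, bIso = -3, table = tab), "B_iso")
})

test_that("f(0) equals Z and unknown elements error", {
  tab <- scatteringTable()
  expect_equal(electronCount(tab, "C"), 6, tolerance = 0.02)
  expect_equal(electronCount(tab, "O"), 8, tolerance = 0.02)
  expect_equal(electronCount(tab, "S"), 16, tolerance = 0.05)
  expect_error(electronCount(tab, "XX"), "absent")
})
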