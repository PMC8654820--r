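test_that("setUniformBfactor resets every atom and validates input", {
  s <- helixFixture()$structure
  s2 <- setUniformBfactor(s, 2)
  expect_true(all(atoms(s2)$b == 2))
  expect_identical(atoms(setUniformBfactor(s2, 2)), atoms(s2))  # idempotent
  expect_error(setUniformBfactor(s, -1), ">= 0")
  expect_error(setUniformBfactor(s, c(1, 2)), ">= 0")
})

test_that("stripStructure drops waters, hetero, hydrogens", {
  s <- helixFixture()$structure
  at <- atoms(s)
  at <- rbind(at,
              atomRow("O", "O", 1, 1, 1, chain = "W", resno = 900L,
                      resname = "HOH", hetero = TRUE),
              atomRow("ZN", "ZN", 2, 2, 2, chain = "Z", resno = 901L,
                      resname = "ZN", hetero = TRUE),
              atomRow("H", "H", 3, 3, 3, chain = "A", resno = 1L,
                      resname = atoms(s)$resname[1]))
  atoms(s) <- at
  out <- atoms(stripStructure(s))
  expect_false(any(out$resname == "HOH"))
  expect_false(any(out$hetero))
  expect_false(any(out$element %in% c("H", "D")))
  # selective switches
  keepw <- atoms(stripStructure(s, dropWaters = FALSE, dropHetero = TRUE))
  expect_true(any(keepw$resname == "HOH"))
  expect_false(any(keepw$resname == "ZN"))
})

test_that("altloc policy keeps the highest-occupancy conformer", {
  s <- helixFixture()$structure
  at <- atoms(s)
  # duplicate the first atom as two conformers
  a1 <- at[1, , drop = FALSE]; a1$altloc <- "A"; a1$occ <- 0.4
  a2 <- a1; a2$altloc <- "B"; a2$occ <- 0.6; a2$x <- a2$x + 0.8
  at <- rbind(a2, a1, at[-1, , drop = FALSE])
  atoms(s) <- at
  out <- atoms(stripStructure(s))
  expect_equal(nrow(out), nrow(atoms(helixFixture()$structure)))
  kept <- out[out$chain == a1$chain & out$resno == a1$resno &
                out$atom == a1$atom, , drop = FALSE]
  expect_equal(nrow(kept), 1)
  expect_equal(kept$x, a2$x)       # the 0.6-occupancy conformer
  expect_equal(kept$occ, 1)        # renormalized
  expect_equal(kept$altloc, "")
  # "all" leaves both
  both <- atoms(stripStructure(s, altlocPolicy = "all"))
  expect_equal(sum(both$atom == a1$atom & both$resno == a1$resno &
                     both$chain == a1$chain), 2)
})

test_that("splitByElement partitions atoms and reports leftovers", {
  s <- helixFixture()$structure
  at <- atoms(s)
  at <- rbind(at, atomRow("SE", "SE", 5, 5, 5, resno = 999L,
                          resname = "MSE"))
  atoms(s) <- at
  ch <- splitByElement(s, c("C", "N", "O", "S"))
  expect_named(ch, c("C", "N", "O", "S"))
  for (e in names(ch)) {
    ae <- atoms(ch[[e]])
    expect_true(all(ae$element == e))
    expect_equal(nrow(ae), sum(at$element == e))
  }
  left <- attr(ch, "unassigned")
  expect_equal(left$element, "SE")
  expect_equal(sum(vapply(ch, function(x) nrow(atoms(x)), 0L)) + nrow(left),
               nrow(at))
  expect_error(splitByElement(s, character(0)), "non-empty")
})
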