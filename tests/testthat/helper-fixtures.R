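# Shared small fixtures for the test suite.

# a minimal atom table row
atomRow <- function(atom = "C", element = "C", x = 0, y = 0, z = 0,
                    chain = "A", resno = 1L, resname = "ALA", occ = 1,
                    b = 10, altloc = "", hetero = FALSE) {
  data.frame(chain = chain, resno = resno, resname = resname, atom = atom,
             element = element, x = x, y = y, z = z, occ = occ, b = b,
             altloc = altloc, hetero = hetero, stringsAsFactors = FALSE)
}

# two-atom "dipeptide-like" structure in a 16 A cube
dipeptideFixture <- function(b = 20) {
  at <- rbind(atomRow("C", "C", 8, 8, 8, b = b),
              atomRow("N", "N", 9.4, 8, 8, b = b))
  XtalStructure(at, cell = UnitCell(16, 16, 16), spaceGroup = "P 1")
}

# small generated helix + simulated map, cached per session
helixEnv <- new.env(parent = emptyenv())
helixFixture <- function() {
  if (is.null(helixEnv$s)) {
    helixEnv$s <- generateStructure(8, seed = 3)
    helixEnv$map <- simulateObservedMap(helixEnv$s, 1.5,
                                        noiseSigma = 0.03, seed = 9)
  }
  list(structure = helixEnv$s, map = helixEnv$map)
}

# self-consistent pair: observed map IS the calculated map of the model
selfConsistentFixture <- function() {
  if (is.null(helixEnv$selfMap)) {
    s <- helixFixture()$structure
    model <- setUniformBfactor(
      stripStructure(s, dropWaters = TRUE, dropHetero = TRUE,
                     dropHydrogens = TRUE), 2)
    helixEnv$selfMap <- synthesizeMap(model)
  }
  list(structure = helixFixture()$structure, map = helixEnv$selfMap)
}
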