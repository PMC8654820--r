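# Seeded synthetic protein-environment fixture with a single water oxygen
# inside a residue's 12 A box.
#
# The environment is a seven-helix bundle whose central residue sits in a
# box packed to protein-interior atom density (packEnvironment); a 12 A
# box around a residue of an isolated ideal helix would be half solvent,
# which is not the regime of the water-contribution bound. The observed
# map is simulated at 1.0 A from the full structure (water included); the
# calculated maps are band-limited at the 0.5 A grid Nyquist, the
# conventional crystallographic calculated-map synthesis.
#
# Functions here are loaded with source(); they assume BoxCC is attached.

waterOxygenFixture <- function(seed = 1L) {
  composition <- c("LEU", "VAL", "MET", "LYS", "SER", "PHE",
                   "LEU", "VAL", "ALA", "MET", "LYS", "LEU")
  sp <- generateBundle(12, nHelices = 7, helixSpacing = 8,
                       composition = composition,
                       neighborComposition = c("GLY", "ALA"),
                       seed = seed)
  at0 <- atoms(sp)
  ctr <- colMeans(at0[at0$resno == 6 & at0$chain == "A",
                      c("x", "y", "z")])
  sp <- packEnvironment(sp, ctr, targetDensity = 0.062,
                        seed = seed + 500L)
  at <- atoms(sp)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  # first offset giving a contact-distance (1.8-3.5 A), clash-free site
  for (off in list(c(2.5, 1, -1.5), c(-2.5, 1, 1.5), c(1, -2.5, 1.5),
                   c(3, 2, 2), c(-3, -2, 2))) {
    w <- ctr + off
    d <- sqrt(min(colSums((t(xyz) - w)^2)))
    if (d >= 1.8 && d <= 3.5) break
  }
  wat <- data.frame(chain = "W", resno = 801L, resname = "HOH",
                    atom = "O", element = "O", x = w[1], y = w[2],
                    z = w[3], occ = 1, b = 20, altloc = "",
                    hetero = TRUE, stringsAsFactors = FALSE)
  atoms(sp) <- rbind(at, wat)
  obsMap <- simulateObservedMap(sp, 1.0, noiseSigma = 0.05,
                                seed = seed + 100L)
  list(structure = sp, obsMap = obsMap, chain = "A", resno = 6L,
       selector = list(resname = "HOH", atom = "O"))
}

# 100 * |delta bCC| / bCC for removing the water oxygen from the
# calculated-density channel
waterOxygenContribution <- function(seed = 1L) {
  fx <- waterOxygenFixture(seed)
  100 * singleAtomContribution(fx$structure, fx$obsMap, fx$chain,
                               fx$resno, fx$selector, dMinCalc = 1.0)
}
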