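# Idealized residue templates in a per-residue local frame.
#
# The frame at residue k of the generated helical backbone is
# (e1 = chain direction, e2 = toward the helix axis, e3 = e1 x e2), origin
# at CA. Backbone offsets below were fitted once so that an ideal
# alpha-helix CA trace (radius 2.3 A, twist 100 deg, rise 1.5 A per
# residue) yields N-CA 1.458 A, CA-C 1.525 A, C-N(next) 1.329 A and
# N-CA-C 111 deg. Sidechains extend outward (-e2) as zigzag chains with
# 1.52 A bonds; rings are ideal hexagons. These are geometrically sane
# stand-ins, not rotamer-library conformers.

BB_N  <- c(-0.990775,  1.069605, -0.008562)
BB_C  <- c( 1.359693,  0.510803, -0.464694)
BB_O  <- c( 2.103128, -0.112454, -1.222464)
BB_CB <- c(-0.462376, -1.146451, -0.901531)

unit3 <- function(v) v / sqrt(sum(v^2))

# grow a zigzag chain outward from `from`, alternating tilt
zigzag <- function(from, nsteps, bond = 1.52, phase = 0) {
  dirs <- list(unit3(c(-0.38, -1, -0.30)), unit3(c(0.38, -1, 0.30)))
  out <- matrix(0, nsteps, 3)
  p <- from
  for (i in seq_len(nsteps)) {
    p <- p + bond * dirs[[(i + phase) %% 2 + 1]]
    out[i, ] <- p
  }
  out
}

ringHexagon <- function(attach, bond = 1.39) {
  # attach is a ring vertex; ring extends outward (-e2)
  u <- unit3(c(0, -1, 0.15))
  v <- unit3(c(1, 0.15, 0))
  v <- unit3(v - sum(v * u) * u)
  ctr <- attach + bond * u
  ang <- pi + seq(0, by = pi / 3, length.out = 6)   # vertex 1 == attach
  t(ctr + t(bond * outer(cos(ang), u) + bond * outer(sin(ang), v)))
}

buildTemplates <- function() {
  bb <- function() setNames(data.frame(
    atom = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
    rbind(N = BB_N, CA = c(0, 0, 0), C = BB_C, O = BB_O)),
    c("atom", "element", "x", "y", "z"))
  add <- function(df, atom, element, xyz) {
    xyz <- matrix(xyz, ncol = 3)
    rbind(df, setNames(data.frame(atom, element, xyz), names(df)))
  }
  t <- list()
  t$GLY <- bb()
  t$ALA <- add(bb(), "CB", "C", BB_CB)
  t$SER <- add(t$ALA, "OG", "O", BB_CB + 1.42 * unit3(c(-0.38, -1, -0.30)))
  { z <- zigzag(BB_CB, 1)
    t$VAL <- add(add(t$ALA, "CG1", "C",
                     BB_CB + 1.52 * unit3(c(-0.95, -1, 0.25))),
                 "CG2", "C", BB_CB + 1.52 * unit3(c(0.95, -1, 0.25))) }
  { z <- zigzag(BB_CB, 1)
    leu <- add(t$ALA, "CG", "C", z[1, ])
    leu <- add(leu, "CD1", "C", z[1, ] + 1.52 * unit3(c(-0.95, -1, 0.25)))
    t$LEU <- add(leu, "CD2", "C", z[1, ] + 1.52 * unit3(c(0.95, -1, 0.25))) }
  { z <- zigzag(BB_CB, 1)
    ring <- ringHexagon(z[1, ])
    phe <- add(t$ALA, "CG", "C", z[1, ])
    nms <- c("CD1", "CE1", "CZ", "CE2", "CD2")
    for (i in 1:5) phe <- add(phe, nms[i], "C", ring[i + 1, ])
    t$PHE <- phe }
  { z <- zigzag(BB_CB, 4)
    lys <- t$ALA
    nms <- c("CG", "CD", "CE", "NZ"); els <- c("C", "C", "C", "N")
    for (i in 1:4) lys <- add(lys, nms[i], els[i], z[i, ])
    t$LYS <- lys }
  { cg <- BB_CB + 1.52 * unit3(c(-0.38, -1, -0.30))
    sd <- cg + 1.80 * unit3(c(0.38, -1, 0.30))
    ce <- sd + 1.80 * unit3(c(-0.38, -1, -0.30))
    met <- add(t$ALA, "CG", "C", cg)
    met <- add(met, "SD", "S", sd)
    t$MET <- add(met, "CE", "C", ce) }
  lapply(t, function(df) { rownames(df) <- NULL; df })
}

templateCache <- new.env(parent = emptyenv())

#' Idealized residue templates of the synthetic generator
#'
#' Eight amino-acid types (Gly, Ala, Ser, Val, Leu, Phe, Lys, Met) with
#' non-hydrogen atoms in a local attachment frame (N, CA, C define the
#' backbone). Covalent backbone bonds lie in 1.3-1.6 A.
#'
#' @return named list of data.frames (atom, element, x, y, z)
#' @export
residueTemplates <- function() {
  if (is.null(templateCache$t)) templateCache$t <- buildTemplates()
  templateCache$t
}
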