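#' Construct a unit cell
#'
#' @param a,b,c edge lengths in Angstrom
#' @param alpha,beta,gamma angles in degrees
#' @return a [UnitCell-class]
#' @examples
#' UnitCell(20, 30, 40)
#' @export
UnitCell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  new("UnitCell", a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
      alpha = as.numeric(alpha), beta = as.numeric(beta),
      gamma = as.numeric(gamma))
}

#' Orthogonalization and fractionalization matrices
#'
#' `orthMatrix` maps fractional to orthogonal Angstrom coordinates using the
#' PDB convention (a along x, b in the xy plane); `fracMatrix` is its inverse.
#' Positions are column vectors: `x_orth = orthMatrix(cell) %*% x_frac`.
#'
#' @param cell a [UnitCell-class]
#' @return a 3 x 3 numeric matrix
#' @export
orthMatrix <- function(cell) {
  stopifnot(is(cell, "UnitCell"))
  d2r <- pi / 180
  ca <- cos(cell@alpha * d2r); cb <- cos(cell@beta * d2r)
  cg <- cos(cell@gamma * d2r); sg <- sin(cell@gamma * d2r)
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  matrix(c(cell@a, cell@b * cg, cell@c * cb,
           0,       cell@b * sg, cell@c * (ca - cb * cg) / sg,
           0,       0,           cell@c * v / sg),
         nrow = 3, byrow = TRUE)
}

#' @rdname orthMatrix
#' @export
fracMatrix <- function(cell) solve(orthMatrix(cell))

#' Unit-cell volume in cubic Angstrom
#' @param cell a [UnitCell-class]
#' @export
cellVolume <- function(cell) {
  det(orthMatrix(cell))
}

#' Convert between fractional and orthogonal coordinates
#'
#' @param cell a [UnitCell-class]
#' @param xyz numeric matrix (n x 3) or vector of length 3
#' @return matrix (n x 3) of converted coordinates
#' @export
orthogonalize <- function(cell, xyz) {
  xyz <- rbind2mat(xyz)
  t(orthMatrix(cell) %*% t(xyz))
}

#' @rdname orthogonalize
#' @export
fractionalize <- function(cell, xyz) {
  xyz <- rbind2mat(xyz)
  t(fracMatrix(cell) %*% t(xyz))
}

rbind2mat <- function(xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  storage.mode(xyz) <- "double"
  xyz
}

#' Reciprocal-space metric: 1/d^2 for Miller indices
#'
#' @param cell a [UnitCell-class]
#' @param hkl integer matrix (m x 3)
#' @return numeric vector of 1/d_hkl^2 (inverse square Angstrom)
#' @export
invResolutionSq <- function(cell, hkl) {
  hkl <- rbind2mat(hkl)
  # rows of fracMatrix are the reciprocal basis vectors a*, b*, c*
  astar <- fracMatrix(cell)
  g <- astar %*% t(astar)   # reciprocal metric tensor
  rowSums((hkl %*% g) * hkl)
}
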