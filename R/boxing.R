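#' Centroid of a residue
#'
#' Unweighted mean of the non-hydrogen atom positions (the box center used
#' throughout). A flag switches to mass-weighting.
#'
#' @param residue atom data.frame (rows of one residue)
#' @param massWeighted weight positions by atomic mass
#' @return numeric length-3 orthogonal coordinates (Angstrom)
#' @export
residueCentroid <- function(residue, massWeighted = FALSE) {
  at <- residue[!(residue$element %in% c("H", "D")), , drop = FALSE]
  if (!nrow(at)) stop("residue has no non-hydrogen atoms")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (massWeighted) {
    mass <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974)
    w <- mass[at$element]
    if (anyNA(w)) stop("no mass for element(s): ",
                       paste(unique(at$element[is.na(w)]), collapse = ", "))
    colSums(xyz * w) / sum(w)
  } else {
    colMeans(xyz)
  }
}

#' Extract a cubic box from a periodic map
#'
#' Samples the map by trilinear interpolation (in fractional space, fully
#' periodic) at N = edge/spacing points per axis along the orthogonal
#' Cartesian axes, placed symmetrically about the center: position
#' center + (i - (N-1)/2) * spacing, i = 0..N-1.
#'
#' @param map a [DensityMap-class]
#' @param center orthogonal box center (Angstrom)
#' @param edge box edge length (Angstrom), default 12
#' @param spacing sample spacing (Angstrom), default 0.5; must divide edge
#' @param provenance label stored on the box
#' @return a [VoxelBox-class] with N^3 values
#' @export
extractBox <- function(map, center, edge = 12.0, spacing = 0.5,
                       provenance = "") {
  n <- edge / spacing
  if (abs(n - round(n)) > 1e-9)
    stop("edge must be an integer multiple of spacing")
  n <- as.integer(round(n))
  off <- (seq_len(n) - 1 - (n - 1) / 2) * spacing
  pts <- as.matrix(expand.grid(x = off, y = off, z = off))
  pts <- sweep(pts, 2, as.numeric(center), "+")
  fr <- fractionalize(map@cell, pts)
  d <- dim(map@values)
  vals <- cpp_trilinear(as.numeric(map@values), d[1], d[2], d[3], fr)
  VoxelBox(array(vals, c(n, n, n)), edge, spacing, center, provenance)
}

#' The 24 proper rotations of the cube
#'
#' Generated by closing the group spanned by the 90-degree rotations about
#' x and z. Each element is orthogonal with determinant +1; together they
#' form the octahedral rotation group used for data augmentation.
#'
#' @return list of 24 integer 3x3 matrices (identity first)
#' @export
cubeRotations <- function() {
  rx <- matrix(c(1, 0, 0,  0, 0, -1,  0, 1, 0), 3, 3, byrow = TRUE)
  rz <- matrix(c(0, -1, 0,  1, 0, 0,  0, 0, 1), 3, 3, byrow = TRUE)
  seen <- list(diag(3))
  keys <- paste(diag(3), collapse = ",")
  i <- 1
  while (i <= length(seen)) {
    for (g in list(rx, rz)) {
      m <- g %*% seen[[i]]
      k <- paste(m, collapse = ",")
      if (!(k %in% keys)) {
        seen[[length(seen) + 1]] <- m
        keys <- c(keys, k)
      }
    }
    i <- i + 1
  }
  stopifnot(length(seen) == 24)
  # identity first, rest in generation order
  lapply(seen, function(m) { storage.mode(m) <- "integer"; m })
}

# voxel index remap for rotation k of an N^3 grid (cached per (N, k))
rotationIndexCache <- new.env(parent = emptyenv())

rotationIndex <- function(n, k) {
  key <- paste(n, k)
  cached <- rotationIndexCache[[key]]
  if (!is.null(cached)) return(cached)
  R <- cubeRotations()[[k + 1L]]
  io <- 0:(n - 1)
  i1 <- rep(io, times = n * n)
  i2 <- rep(rep(io, each = n), times = n)
  i3 <- rep(io, each = n * n)
  iout <- list(i1, i2, i3)
  idx_in <- vector("list", 3)
  for (d in 1:3) {
    e <- which(R[, d] != 0)       # c_in[d] = R[e, d] * c_out[e]
    s <- R[e, d]
    j <- iout[[e]]
    idx_in[[d]] <- if (s > 0) j else (n - 1) - j
  }
  lin <- idx_in[[1]] + n * (idx_in[[2]] + n * idx_in[[3]]) + 1L
  rotationIndexCache[[key]] <- lin
  lin
}

#' Rotate a voxel box by one of the 24 cube rotations
#'
#' Pure index permutation (no interpolation): the voxel multiset is
#' preserved exactly, and rotation 0 is the identity.
#'
#' @param box a [VoxelBox-class] (or bare cubic array)
#' @param index rotation index 0..23 into [cubeRotations()]
#' @return object of the same kind as `box`
#' @export
rotateBox <- function(box, index) {
  if (length(index) != 1 || is.na(index) || index < 0 || index > 23)
    stop("rotation index must be in 0..23")
  arr <- if (is(box, "VoxelBox")) box@values else box
  n <- dim(arr)[1]
  out <- array(arr[rotationIndex(n, as.integer(index))], dim(arr))
  if (is(box, "VoxelBox")) {
    box@values <- out
    box
  } else out
}
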