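#' Synthesize a unit-cell electron density map from coordinates
#'
#' Real-space Gaussian summation: the map value at each grid point is the sum
#' over atoms (and their periodic images) of occupancy times the atomic
#' density [atomicDensity()] at the point-atom distance. Each atom
#' contributes out to the radius where its density falls below `cutoffRel`
#' times its peak value, which bounds cost while keeping the truncation error
#' below float32 map precision.
#'
#' @param structure an [XtalStructure-class] with a P1 cell
#' @param dims grid dimensions c(nx, ny, nz); default gives spacing <= 0.5 A
#' @param bOverride single B factor applied to all atoms (Angstrom^2), or
#'   NULL to use each atom's own
#' @param table a [ScatteringTable-class]
#' @param cutoffRel relative density cutoff for atom contributions
#' @param provenance label for the returned map
#' @return a [DensityMap-class]
#' @export
synthesizeMap <- function(structure, dims = NULL, bOverride = NULL,
                          table = scatteringTable(), cutoffRel = 1e-6,
                          provenance = "calculated") {
  cell <- requireP1Cell(structure)
  if (is.null(dims)) dims <- gridDimsForSpacing(cell, 0.5)
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(dims < 1))
    stop("grid dims must be 3 positive integers")
  sp <- c(cell@a, cell@b, cell@c) / dims
  if (any(sp > 0.5 + 1e-9))
    warning(sprintf("grid spacing up to %.2f A is coarser than the 0.5 A recommended for box extraction", max(sp)))
  at <- atoms(structure)
  if (!nrow(at))
    return(DensityMap(array(0, dims), cell, provenance = provenance))
  b <- if (is.null(bOverride)) at$b else rep(as.numeric(bOverride), nrow(at))
  cf <- tableForCpp(table, at$element)
  vals <- cpp_synth_map(as.matrix(at[, c("x", "y", "z")]), at$occ, b,
                        cf$elem0, cf$a, cf$b, orthMatrix(cell),
                        fracMatrix(cell), dims[1], dims[2], dims[3],
                        cutoffRel)
  DensityMap(array(vals, dims), cell, provenance = provenance)
}

requireP1Cell <- function(structure) {
  cell <- unitCell(structure)
  if (is.null(cell)) stop("structure has no unit cell")
  if (gsub(" ", "", structure@spaceGroup) != "P1")
    stop("only P1 structures are synthesized internally; expand symmetry ",
         "externally first (space group was '", structure@spaceGroup, "')")
  cell
}

#' Grid dimensions for a target spacing
#'
#' Smallest even dimensions giving a sample spacing at or below `spacing`
#' along every cell edge.
#'
#' @param cell a [UnitCell-class]
#' @param spacing target spacing in Angstrom
#' @export
gridDimsForSpacing <- function(cell, spacing = 0.5) {
  n <- ceiling(c(cell@a, cell@b, cell@c) / spacing)
  as.integer(n + n %% 2)
}

#' Enumerate Miller indices to a resolution limit
#'
#' All (h, k, l) with d >= dMin, including F(000) and both Friedel mates.
#'
#' @param cell a [UnitCell-class]
#' @param dMin resolution limit in Angstrom
#' @return integer matrix (m x 3)
#' @export
enumerateHkl <- function(cell, dMin) {
  if (dMin <= 0) stop("dMin must be > 0")
  hmax <- ceiling(c(cell@a, cell@b, cell@c) / dMin) + 1L
  hkl <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                               l = -hmax[3]:hmax[3]))
  q2 <- invResolutionSq(cell, hkl)
  keep <- q2 <= 1 / dMin^2 + 1e-12
  m <- hkl[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

#' Structure factors by direct summation
#'
#' F(h) = sum over atoms of occ * f_el(q) * exp(2 pi i h . x_frac) with
#' f_el(q) = sum_i a_i exp(-(b_i + B) q^2 / 4), q = 1/d. F(000) equals the
#' total model electron count.
#'
#' @inheritParams synthesizeMap
#' @param dMin resolution limit in Angstrom (> 0)
#' @return a [ReflectionSet-class] containing every reflection with
#'   d >= dMin (both Friedel mates and F(000))
#' @export
structureFactors <- function(structure, dMin, bOverride = NULL,
                             table = scatteringTable()) {
  cell <- requireP1Cell(structure)
  if (dMin <= 0) stop("dMin must be > 0")
  hkl <- enumerateHkl(cell, dMin)
  at <- atoms(structure)
  if (!nrow(at))
    return(ReflectionSet(hkl, complex(real = numeric(nrow(hkl))), cell, dMin))
  b <- if (is.null(bOverride)) at$b else rep(as.numeric(bOverride), nrow(at))
  cf <- tableForCpp(table, at$element)
  fx <- fractionalize(cell, as.matrix(at[, c("x", "y", "z")]))
  q2 <- invResolutionSq(cell, hkl)
  f <- cpp_structure_factors(rbind2mat(hkl), q2, fx, at$occ, b,
                             cf$elem0, cf$a, cf$b)
  ReflectionSet(hkl, f, cell, dMin)
}

#' Fourier synthesis of a density map from structure factors
#'
#' rho(x) = (1/V) sum_h F(h) exp(-2 pi i h . x), evaluated by FFT on the
#' requested grid. The grid must satisfy the Nyquist bound
#' dim >= 2 * cell_edge / dMin along each axis.
#'
#' @param reflections a [ReflectionSet-class] (Friedel-complete for a real
#'   map; a half set is completed automatically by conjugate symmetry)
#' @param dims grid dimensions c(nx, ny, nz); default oversamples 1.5x
#'   Nyquist (3 samples per dMin)
#' @param provenance label for the returned map
#' @return a real [DensityMap-class]
#' @export
mapFromReflections <- function(reflections, dims = NULL,
                               provenance = "calculated") {
  stopifnot(is(reflections, "ReflectionSet"))
  cell <- reflections@cell
  if (is.null(dims)) dims <- gridDimsForDmin(cell, reflections@dMin)
  dims <- as.integer(dims)
  nyq <- 2 * c(cell@a, cell@b, cell@c) / reflections@dMin
  if (any(dims < floor(nyq)))
    stop(sprintf("grid %dx%dx%d too coarse for d_min %.2f A (need >= %d %d %d)",
                 dims[1], dims[2], dims[3], reflections@dMin,
                 ceiling(nyq)[1], ceiling(nyq)[2], ceiling(nyq)[3]))
  hkl <- reflections@hkl
  f <- reflections@f
  # complete Friedel mates absent from the set
  key <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  negkey <- paste(-hkl[, 1], -hkl[, 2], -hkl[, 3])
  miss <- !(negkey %in% key)
  if (any(miss)) {
    hkl <- rbind(hkl, -hkl[miss, , drop = FALSE])
    f <- c(f, Conj(f[miss]))
  }
  grid <- array(0 + 0i, dims)
  idx <- cbind(hkl[, 1] %% dims[1], hkl[, 2] %% dims[2],
               hkl[, 3] %% dims[3]) + 1L
  if (any(duplicated(idx %*% c(1, dims[1], dims[1] * dims[2]))))
    stop("grid too coarse: distinct reflections alias to one grid point")
  grid[idx] <- f
  rho <- stats::fft(grid) / cellVolume(cell)
  rel <- max(abs(Im(rho))) / max(abs(Re(rho)), .Machine$double.eps)
  if (rel > 1e-8)
    warning(sprintf("non-negligible imaginary component (relative %.2g); input may violate Friedel symmetry", rel))
  DensityMap(array(Re(rho), dims), cell, provenance = provenance)
}

#' Grid dimensions oversampling a resolution limit
#'
#' Smallest even dimensions with at least 3 samples per dMin (1.5x Nyquist),
#' limiting aliasing in truncated maps.
#'
#' @param cell a [UnitCell-class]
#' @param dMin resolution limit in Angstrom
#' @export
gridDimsForDmin <- function(cell, dMin) {
  n <- ceiling(3 * c(cell@a, cell@b, cell@c) / dMin)
  as.integer(n + n %% 2)
}

#' Truncate a reflection set to lower resolution
#'
#' Keeps exactly the reflections with d >= dMinNew (F(000) always survives);
#' surviving structure factors are untouched. This is the simulator's stand-in
#' for collecting data to a poorer resolution limit.
#'
#' @param reflections a [ReflectionSet-class]
#' @param dMinNew new resolution limit, >= the current one
#' @return a [ReflectionSet-class]
#' @export
truncateResolution <- function(reflections, dMinNew) {
  if (dMinNew < reflections@dMin)
    stop(sprintf("dMinNew (%.3f) must be >= current dMin (%.3f)",
                 dMinNew, reflections@dMin))
  q2 <- invResolutionSq(reflections@cell, reflections@hkl)
  keep <- q2 <= 1 / dMinNew^2 + 1e-12
  ReflectionSet(reflections@hkl[keep, , drop = FALSE], reflections@f[keep],
                reflections@cell, dMinNew)
}

#' Add complex Gaussian noise to structure factors
#'
#' Each reflection except F(000) is perturbed by complex Gaussian noise with
#' standard deviation `relativeSigma * RMS(|F|)` (RMS over non-F(000)
#' reflections). Friedel symmetry is preserved by perturbing each Friedel
#' pair with conjugate noise. Deterministic under a fixed seed.
#'
#' @param reflections a [ReflectionSet-class]
#' @param relativeSigma noise level relative to the RMS structure-factor
#'   amplitude, >= 0
#' @param seed integer RNG seed
#' @return a [ReflectionSet-class]
#' @export
addReflectionNoise <- function(reflections, relativeSigma, seed = 1L) {
  if (relativeSigma < 0) stop("relativeSigma must be >= 0")
  if (relativeSigma == 0) return(reflections)
  hkl <- reflections@hkl
  f <- reflections@f
  notf0 <- rowSums(abs(hkl)) > 0
  sigma <- relativeSigma * sqrt(mean(Mod(f[notf0])^2))
  # key each Friedel pair by its lexicographically positive member
  sgn <- ifelse(hkl[, 1] != 0, sign(hkl[, 1]),
                ifelse(hkl[, 2] != 0, sign(hkl[, 2]), sign(hkl[, 3])))
  rep_hkl <- hkl * ifelse(sgn < 0, -1L, 1L)
  key <- paste(rep_hkl[, 1], rep_hkl[, 2], rep_hkl[, 3])
  ukey <- unique(key[notf0])
  rng <- withSeed(seed, {
    matrix(rnorm(2L * length(ukey), sd = sigma / sqrt(2)), ncol = 2)
  })
  noise <- complex(real = rng[, 1], imaginary = rng[, 2])[match(key, ukey)]
  noise[!notf0] <- 0
  conj <- sgn < 0
  noise[conj] <- Conj(noise[conj])
  ReflectionSet(hkl, f + noise, reflections@cell, reflections@dMin)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read and write reflection sets as columnar text
#'
#' Plain whitespace-separated columns `h k l F_real F_imag` with a commented
#' header carrying the cell and resolution limit.
#'
#' @param reflections a [ReflectionSet-class]
#' @param path file path
#' @return `writeReflections` returns `path` invisibly; `readReflections`
#'   returns a [ReflectionSet-class]
#' @export
writeReflections <- function(reflections, path) {
  cl <- reflections@cell
  hdr <- c(sprintf("# cell %.6f %.6f %.6f %.6f %.6f %.6f",
                   cl@a, cl@b, cl@c, cl@alpha, cl@beta, cl@gamma),
           sprintf("# dmin %.6f", reflections@dMin),
           "# h k l F_real F_imag")
  df <- data.frame(h = reflections@hkl[, 1], k = reflections@hkl[, 2],
                   l = reflections@hkl[, 3],
                   fr = Re(reflections@f), fi = Im(reflections@f))
  writeLines(hdr, path)
  write.table(format(df, digits = 12, scientific = TRUE, trim = TRUE),
              path, append = TRUE, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeReflections
#' @export
readReflections <- function(path) {
  hdr <- readLines(path, n = 10L)
  cellln <- grep("^# cell ", hdr, value = TRUE)[1]
  dminln <- grep("^# dmin ", hdr, value = TRUE)[1]
  if (is.na(cellln) || is.na(dminln))
    stop("missing '# cell' or '# dmin' header in ", path)
  cv <- as.numeric(strsplit(trimws(sub("^# cell ", "", cellln)), " +")[[1]])
  cell <- UnitCell(cv[1], cv[2], cv[3], cv[4], cv[5], cv[6])
  dmin <- as.numeric(sub("^# dmin ", "", dminln))
  df <- read.table(path, comment.char = "#")
  ReflectionSet(as.matrix(df[, 1:3]),
                complex(real = df[, 4], imaginary = df[, 5]), cell, dmin)
}
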