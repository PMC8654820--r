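#' Crystallographic unit cell
#'
#' Lengths in Angstrom, angles in degrees. The orthogonalization convention is
#' the PDB standard: a along x, b in the xy plane, right-handed frame.
#'
#' @slot a,b,c cell edge lengths (Angstrom)
#' @slot alpha,beta,gamma cell angles (degrees), each in (0, 180)
#' @export
setClass("UnitCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric"),
  validity = function(object) {
    len <- c(object@a, object@b, object@c)
    ang <- c(object@alpha, object@beta, object@gamma)
    if (any(!is.finite(len)) || any(len <= 0))
      return("cell lengths must be finite and > 0")
    if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
      return("cell angles must lie in (0, 180) degrees")
    ca <- cos(ang * pi / 180)
    disc <- 1 - sum(ca^2) + 2 * prod(ca)
    if (disc <= 0) return("cell angles do not define a positive cell volume")
    TRUE
  })

setClassUnion("UnitCellOrNULL", c("UnitCell", "NULL"))

#' Atomic model of a crystal asymmetric unit (P1 for synthesis)
#'
#' Atoms are held in a data.frame with columns `chain`, `resno`, `resname`,
#' `atom` (atom name), `element`, `x`, `y`, `z` (orthogonal Angstrom), `occ`,
#' `b` (isotropic B, Angstrom^2), `altloc` ("" when absent) and `hetero`
#' (logical; HETATM records, including waters).
#'
#' @slot cell a [UnitCell-class] or NULL when the source file carried none
#' @slot spaceGroup space group symbol; only "P 1" maps are synthesized
#' @slot atoms the atom table (see Description)
#' @export
setClass("XtalStructure",
  representation(cell = "UnitCellOrNULL", spaceGroup = "character",
                 atoms = "data.frame"),
  validity = function(object) {
    need <- c("chain", "resno", "resname", "atom", "element",
              "x", "y", "z", "occ", "b", "altloc", "hetero")
    miss <- setdiff(need, names(object@atoms))
    if (length(miss)) return(paste("atom table lacks columns:",
                                   paste(miss, collapse = ", ")))
    at <- object@atoms
    if (nrow(at)) {
      if (any(!is.finite(at$b)) || any(at$b < 0))
        return("B factors must be finite and >= 0")
      if (any(!is.finite(at$occ)) || any(at$occ < 0) || any(at$occ > 1))
        return("occupancies must lie in [0, 1]")
      if (any(!is.finite(as.matrix(at[, c("x", "y", "z")]))))
        return("coordinates must be finite")
    }
    TRUE
  })

#' Electron density map on a periodic unit-cell grid
#'
#' Values are sampled on the fractional-coordinate grid: point (i, j, k)
#' (0-based) sits at fractional (i/nx, j/ny, k/nz); sampling is periodic in
#' every axis. Internal axis order is always a, b, c with a fastest,
#' regardless of the order in any source file.
#'
#' @slot cell the [UnitCell-class] the grid spans
#' @slot values numeric 3D array, dim = c(nx, ny, nz)
#' @slot provenance free-text label ("observed", "calculated", "synthetic", ...)
#' @export
setClass("DensityMap",
  representation(cell = "UnitCell", values = "array", provenance = "character"),
  validity = function(object) {
    if (length(dim(object@values)) != 3) return("values must be a 3D array")
    if (any(dim(object@values) < 1)) return("grid dimensions must be >= 1")
    if (!all(is.finite(object@values))) return("map values must be finite")
    TRUE
  })

#' Set of structure factors for a P1 cell
#'
#' Friedel-unique reflections are not enforced; real maps require
#' F(-h,-k,-l) = Conj(F(h,k,l)), which all constructors in this package
#' guarantee by generating full Friedel pairs.
#'
#' @slot cell the [UnitCell-class]
#' @slot hkl integer matrix (m x 3) of Miller indices, unique rows
#' @slot f complex structure factors (electrons)
#' @slot dMin resolution limit in Angstrom (d spacing of the finest reflection
#'   requested at generation time)
#' @export
setClass("ReflectionSet",
  representation(cell = "UnitCell", hkl = "matrix", f = "complex",
                 dMin = "numeric"),
  validity = function(object) {
    if (ncol(object@hkl) != 3) return("hkl must have 3 columns")
    if (nrow(object@hkl) != length(object@f))
      return("hkl and f lengths differ")
    if (anyDuplicated(object@hkl)) return("duplicate Miller indices")
    if (length(object@dMin) != 1 || object@dMin <= 0)
      return("dMin must be a single positive number")
    TRUE
  })

#' Gaussian scattering-factor table
#'
#' Five-term Gaussian parameterization per element. The tabulated constant
#' scattering term is folded in as the fifth Gaussian with b = 0, whose
#' real-space width is then set by B_iso alone; this preserves f(0) = Z.
#'
#' @slot elements element symbols (columns of `a` and `b`)
#' @slot a 5 x n matrix of Gaussian amplitudes (electrons)
#' @slot b 5 x n matrix of Gaussian widths (Angstrom^2); the fold-in term has 0
#' @slot constantFoldIn TRUE when the constant term occupies the last row
#' @slot version identifier of the coefficient source file
#' @export
setClass("ScatteringTable",
  representation(elements = "character", a = "matrix", b = "matrix",
                 constantFoldIn = "logical", version = "character"),
  validity = function(object) {
    if (!identical(dim(object@a), dim(object@b)))
      return("a and b coefficient matrices differ in shape")
    if (ncol(object@a) != length(object@elements))
      return("element count does not match coefficient columns")
    if (any(object@b < 0)) return("Gaussian widths must be >= 0")
    ngauss <- nrow(object@b) - as.integer(isTRUE(object@constantFoldIn))
    if (ngauss > 0 && any(object@b[seq_len(ngauss), , drop = FALSE] <= 0))
      return("non-constant Gaussian terms must have b > 0")
    TRUE
  })

#' Cubic voxel box extracted around a residue
#'
#' @slot values numeric N x N x N array of density samples (e/Angstrom^3)
#' @slot edge box edge length (Angstrom)
#' @slot spacing sample spacing (Angstrom); N = edge / spacing
#' @slot center orthogonal coordinates of the box center (Angstrom)
#' @slot provenance residue id and source map label
#' @export
setClass("VoxelBox",
  representation(values = "array", edge = "numeric", spacing = "numeric",
                 center = "numeric", provenance = "character"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3 || length(unique(d)) != 1)
      return("box must be a cubic 3D array")
    n <- object@edge / object@spacing
    if (abs(n - round(n)) > 1e-9)
      return("edge must be an integer multiple of spacing")
    if (round(n) != d[1])
      return("array dimension does not equal edge/spacing")
    if (!all(is.finite(object@values))) return("box values must be finite")
    if (length(object@center) != 3) return("center must have 3 coordinates")
    TRUE
  })

#' Five-channel voxel descriptor of one residue
#'
#' Channel 1 holds the boxed observed map; channels 2-5 hold calculated
#' density of the C, N, O and S atoms of the (B-reset, stripped) model.
#'
#' @slot channels numeric array, dim = c(N, N, N, 5)
#' @slot label bCC_act in \[-1, 1\], or NA when unlabeled/degenerate
#' @slot meta list: `aa` (three-letter code), `chain`, `resno`, `structureId`,
#'   `resolutionTag`, `flag`
#' @export
setClass("DescriptorRecord",
  representation(channels = "array", label = "numeric", meta = "list"),
  validity = function(object) {
    d <- dim(object@channels)
    if (length(d) != 4 || d[4] != 5)
      return("channels must be an N x N x N x 5 array")
    if (length(unique(d[1:3])) != 1) return("channel grids must be cubic")
    if (length(object@label) != 1) return("label must have length 1")
    if (!is.na(object@label) && abs(object@label) > 1 + 1e-9)
      return("label must lie in [-1, 1]")
    TRUE
  })

#' On-disk archive of labeled descriptors
#'
#' A directory with one chunk file per amino-acid type plus a JSON manifest
#' recording counts, the label histogram and full generator provenance.
#'
#' @slot path archive directory
#' @slot manifest parsed manifest list
#' @export
setClass("DescriptorArchive",
  representation(path = "character", manifest = "list"))

#' Configuration of the 3D convolutional bCC regressor
#'
#' Exactly four fire stages (1^3 squeeze convolution + 3^3 expand
#' convolution); dropout is architecturally fixed before the last stage's
#' convolutions; pooling per stage is none/max/average.
#'
#' @slot inputN samples per box axis
#' @slot channels input channel count (5)
#' @slot squeeze,expand per-stage filter counts (length 4)
#' @slot pool per-stage pooling: 0 none, 1 max 2^3, 2 average 2^3 (length 4)
#' @slot dropout dropout rate before the last stage
#' @slot lr Adam learning rate
#' @slot epochs training epochs
#' @slot batchSize mini-batch size
#' @slot seed RNG seed for init, shuffling and dropout
#' @slot normalize per-channel z-scoring with training-set statistics
#' @slot augment number of cube rotations per record during training (1..24)
#' @export
setClass("CNNConfig",
  representation(inputN = "integer", channels = "integer",
                 squeeze = "integer", expand = "integer", pool = "integer",
                 dropout = "numeric", lr = "numeric", epochs = "integer",
                 batchSize = "integer", seed = "integer",
                 normalize = "logical", augment = "integer"),
  validity = function(object) {
    if (length(object@squeeze) != 4 || length(object@expand) != 4 ||
        length(object@pool) != 4)
      return("exactly 4 convolutional stages are required")
    if (object@lr <= 0) return("learning rate must be > 0")
    if (object@dropout < 0 || object@dropout >= 1)
      return("dropout must lie in [0, 1)")
    if (!all(object@pool %in% 0:2)) return("pool codes must be 0, 1 or 2")
    np <- sum(object@pool != 0)
    if (object@inputN %% 2^np != 0)
      return("inputN must be divisible by 2^(number of pooled stages)")
    if (object@augment < 1L || object@augment > 24L)
      return("augment must be in 1..24")
    TRUE
  })

#' Trained per-amino-acid bCC regressor
#'
#' @slot aminoAcid three-letter code the model applies to
#' @slot weights network weights (list of stages + linear head)
#' @slot config the [CNNConfig-class] used
#' @slot history training loss per epoch
#' @slot normStats per-channel mean/sd used for input normalization
#' @slot manifestHash hash of the training archive manifest
#' @export
setClass("TrainedModel",
  representation(aminoAcid = "character", weights = "list",
                 config = "CNNConfig", history = "numeric",
                 normStats = "list", manifestHash = "character"))
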