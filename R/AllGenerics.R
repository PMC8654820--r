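#' @name BoxCC-generics
#' @title Accessor generics
#' @description Small accessor generics shared by the core classes.
#' @param x an object
#' @param value replacement value
#' @aliases atoms,XtalStructure-method atoms<-,XtalStructure-method
#'   boxValues,VoxelBox-method dMin,ReflectionSet-method
#'   gridDims,DensityMap-method mapValues,DensityMap-method
#'   provenance,DensityMap-method provenance,VoxelBox-method
#'   reflections,ReflectionSet-method unitCell,DensityMap-method
#'   unitCell,ReflectionSet-method unitCell,XtalStructure-method
NULL

#' @rdname BoxCC-generics
#' @export
setGeneric("unitCell", function(x) standardGeneric("unitCell"))

#' @rdname BoxCC-generics
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname BoxCC-generics
#' @export
setGeneric("atoms<-", function(x, value) standardGeneric("atoms<-"))

#' @rdname BoxCC-generics
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname BoxCC-generics
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))

#' @rdname BoxCC-generics
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname BoxCC-generics
#' @export
setGeneric("boxValues", function(x) standardGeneric("boxValues"))

#' @rdname BoxCC-generics
#' @export
setGeneric("reflections", function(x) standardGeneric("reflections"))

#' @rdname BoxCC-generics
#' @export
setGeneric("dMin", function(x) standardGeneric("dMin"))

setMethod("unitCell", "XtalStructure", function(x) x@cell)
setMethod("unitCell", "DensityMap", function(x) x@cell)
setMethod("unitCell", "ReflectionSet", function(x) x@cell)

setMethod("atoms", "XtalStructure", function(x) x@atoms)
setMethod("atoms<-", "XtalStructure", function(x, value) {
  x@atoms <- value
  validObject(x)
  x
})

setMethod("mapValues", "DensityMap", function(x) x@values)
setMethod("gridDims", "DensityMap", function(x) dim(x@values))
setMethod("provenance", "DensityMap", function(x) x@provenance)
setMethod("provenance", "VoxelBox", function(x) x@provenance)
setMethod("boxValues", "VoxelBox", function(x) x@values)

setMethod("reflections", "ReflectionSet", function(x)
  data.frame(h = x@hkl[, 1], k = x@hkl[, 2], l = x@hkl[, 3], f = x@f))
setMethod("dMin", "ReflectionSet", function(x) x@dMin)

setMethod("show", "UnitCell", function(object) {
  cat(sprintf("UnitCell  a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f\n",
              object@a, object@b, object@c,
              object@alpha, object@beta, object@gamma))
})

setMethod("show", "XtalStructure", function(object) {
  at <- object@atoms
  nres <- nrow(unique(at[!at$hetero, c("chain", "resno")]))
  cat(sprintf("XtalStructure  %d atoms, %d protein residues, %d hetero atoms\n",
              nrow(at), nres, sum(at$hetero)))
  if (!is.null(object@cell)) show(object@cell)
  cat("space group:", object@spaceGroup, "\n")
})

setMethod("show", "DensityMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("DensityMap  %dx%dx%d grid (%s)  range [%.4g, %.4g]\n",
              d[1], d[2], d[3], object@provenance,
              min(object@values), max(object@values)))
  show(object@cell)
})

setMethod("show", "ReflectionSet", function(object) {
  cat(sprintf("ReflectionSet  %d reflections to d_min %.2f A\n",
              nrow(object@hkl), object@dMin))
})

setMethod("show", "VoxelBox", function(object) {
  d <- dim(object@values)
  cat(sprintf("VoxelBox  %d^3, edge %.1f A, spacing %.2f A, center (%.2f, %.2f, %.2f)\n",
              d[1], object@edge, object@spacing,
              object@center[1], object@center[2], object@center[3]))
})

setMethod("show", "DescriptorRecord", function(object) {
  d <- dim(object@channels)
  cat(sprintf("DescriptorRecord  %s %s%s  %d^3 x 5 channels, label %s\n",
              object@meta$aa %||% "?", object@meta$chain %||% "?",
              object@meta$resno %||% "?", d[1],
              ifelse(is.na(object@label), "NA", sprintf("%.3f", object@label))))
})

setMethod("show", "DescriptorArchive", function(object) {
  cat(sprintf("DescriptorArchive  %s\n", object@path))
  cnt <- object@manifest$counts
  for (aa in names(cnt)) cat(sprintf("  %s: %d records\n", aa, cnt[[aa]]))
})

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel  %s  (%d epochs, final loss %.4g)\n",
              object@aminoAcid, length(object@history),
              if (length(object@history)) object@history[length(object@history)] else NA))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
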