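#' Construct an atomic structure
#'
#' @param atoms atom data.frame (see [XtalStructure-class] for columns);
#'   missing optional columns (`occ`, `b`, `altloc`, `hetero`) are filled
#'   with defaults 1, 0, "" and FALSE
#' @param cell a [UnitCell-class] or NULL
#' @param spaceGroup space group symbol
#' @return an [XtalStructure-class]
#' @export
XtalStructure <- function(atoms, cell = NULL, spaceGroup = "P 1") {
  defaults <- list(occ = 1, b = 0, altloc = "", hetero = FALSE)
  for (nm in names(defaults))
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$resname <- as.character(atoms$resname)
  atoms$atom <- as.character(atoms$atom)
  atoms$element <- as.character(atoms$element)
  rownames(atoms) <- NULL
  new("XtalStructure", cell = cell, spaceGroup = spaceGroup, atoms = atoms)
}

#' Construct a density map
#'
#' @param values 3D numeric array sampled on the fractional grid
#' @param cell a [UnitCell-class]
#' @param provenance free-text source label
#' @return a [DensityMap-class]
#' @export
DensityMap <- function(values, cell, provenance = "synthetic") {
  new("DensityMap", cell = cell, values = values, provenance = provenance)
}

#' Construct a reflection set
#'
#' @param hkl integer matrix (m x 3) of Miller indices
#' @param f complex structure factors
#' @param cell a [UnitCell-class]
#' @param dMin resolution limit in Angstrom
#' @return a [ReflectionSet-class]
#' @export
ReflectionSet <- function(hkl, f, cell, dMin) {
  hkl <- rbind2mat(hkl)
  storage.mode(hkl) <- "integer"
  new("ReflectionSet", cell = cell, hkl = hkl, f = as.complex(f),
      dMin = as.numeric(dMin))
}

#' Construct a voxel box
#'
#' @param values cubic 3D numeric array
#' @param edge box edge (Angstrom)
#' @param spacing voxel spacing (Angstrom)
#' @param center orthogonal center coordinates (Angstrom)
#' @param provenance residue/source label
#' @return a [VoxelBox-class]
#' @export
VoxelBox <- function(values, edge, spacing, center = c(0, 0, 0),
                     provenance = "") {
  new("VoxelBox", values = values, edge = as.numeric(edge),
      spacing = as.numeric(spacing), center = as.numeric(center),
      provenance = provenance)
}

#' Construct a descriptor record
#'
#' @param channels N x N x N x 5 numeric array
#' @param label bCC_act label (NA when unlabeled)
#' @param meta metadata list (`aa`, `chain`, `resno`, `structureId`,
#'   `resolutionTag`, `flag`)
#' @return a [DescriptorRecord-class]
#' @export
DescriptorRecord <- function(channels, label = NA_real_, meta = list()) {
  new("DescriptorRecord", channels = channels, label = as.numeric(label),
      meta = meta)
}

#' Residue table of a structure
#'
#' One row per residue in file order, with a logical `hetero` column (TRUE
#' when every atom of the residue is a HETATM, e.g. waters and ligands).
#'
#' @param structure an [XtalStructure-class]
#' @return data.frame with columns chain, resno, resname, hetero, nAtoms
#' @export
residueTable <- function(structure) {
  at <- atoms(structure)
  if (!nrow(at))
    return(data.frame(chain = character(), resno = integer(),
                      resname = character(), hetero = logical(),
                      nAtoms = integer()))
  key <- paste(at$chain, at$resno, at$resname, sep = "\r")
  idx <- !duplicated(key)
  out <- data.frame(chain = at$chain[idx], resno = at$resno[idx],
                    resname = at$resname[idx],
                    hetero = as.logical(tapply(at$hetero, key, all)[key[idx]]),
                    nAtoms = as.integer(table(key)[key[idx]]))
  rownames(out) <- NULL
  out
}

#' Extract one residue's atoms
#'
#' @param structure an [XtalStructure-class]
#' @param chain chain identifier
#' @param resno residue number (author numbering)
#' @return atom data.frame subset
#' @export
residueAtoms <- function(structure, chain, resno) {
  at <- atoms(structure)
  at[at$chain == chain & at$resno == resno, , drop = FALSE]
}

#' The 20 standard amino-acid three-letter codes
#' @export
STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")
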