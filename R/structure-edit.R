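#' Set every atom's B factor to one value
#'
#' Calculated density used for bCC scores the coordinates only, so the
#' isotropic displacement parameter is reset to a small uniform value
#' (2.0 Angstrom^2 by convention) before synthesis.
#'
#' @param structure an [XtalStructure-class]
#' @param value B factor in Angstrom^2, >= 0
#' @return the structure with all `b` set to `value`; idempotent
#' @export
setUniformBfactor <- function(structure, value = 2.0) {
  if (!is.numeric(value) || length(value) != 1 || is.na(value) || value < 0)
    stop("B factor must be a single number >= 0")
  at <- atoms(structure)
  at$b <- value
  atoms(structure) <- at
  structure
}

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Remove waters, hetero compounds, hydrogens and alternate conformers
#'
#' `altlocPolicy = "highest_occupancy"` keeps exactly one conformer per
#' (residue, atom name): the one with the highest occupancy, ties broken by
#' the alphabetically first altloc code. The kept conformer's occupancy is
#' set to 1 and its altloc cleared, since the density comparison assumes a
#' single model. `"all"` leaves conformers untouched.
#'
#' @param structure an [XtalStructure-class]
#' @param dropWaters remove water residues (HOH/WAT/DOD)
#' @param dropHetero remove all other HETATM records (ligands, ions)
#' @param dropHydrogens remove hydrogen (and deuterium) atoms
#' @param altlocPolicy "highest_occupancy" or "all"
#' @return the filtered structure (possibly with zero atoms)
#' @export
stripStructure <- function(structure, dropWaters = TRUE, dropHetero = TRUE,
                           dropHydrogens = TRUE,
                           altlocPolicy = c("highest_occupancy", "all")) {
  altlocPolicy <- match.arg(altlocPolicy)
  at <- atoms(structure)
  keep <- rep(TRUE, nrow(at))
  iswat <- at$resname %in% WATER_RESNAMES
  if (dropWaters) keep <- keep & !iswat
  if (dropHetero) keep <- keep & !(at$hetero & !iswat)
  if (dropHydrogens) keep <- keep & !(at$element %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  if (altlocPolicy == "highest_occupancy" && nrow(at)) {
    key <- paste(at$chain, at$resno, at$resname, at$atom, sep = "\r")
    ord <- order(key, -at$occ, at$altloc)
    at <- at[ord, , drop = FALSE]
    dup <- duplicated(key[ord])
    had_alt <- key[ord] %in% key[ord][dup]
    at <- at[!dup, , drop = FALSE]
    sel <- had_alt[!dup] | at$altloc != ""
    at$occ[sel] <- 1
    at$altloc <- ""
    at <- at[order(match(paste(at$chain, at$resno, at$resname, at$atom,
                               sep = "\r"),
                         unique(key))), , drop = FALSE]
  }
  rownames(at) <- NULL
  atoms(structure) <- at
  structure
}

#' Split a structure by chemical element
#'
#' Used to build the per-element calculated-density channels. Atoms whose
#' element is not listed are reported via the `"unassigned"` attribute of
#' the result rather than silently dropped.
#'
#' @param structure an [XtalStructure-class]
#' @param elements non-empty character vector of element symbols
#' @return named list of [XtalStructure-class], one per requested element;
#'   attribute `"unassigned"` holds the atom rows of unlisted elements
#' @examples
#' \dontrun{splitByElement(s, c("C", "N", "O", "S"))}
#' @export
splitByElement <- function(structure, elements = c("C", "N", "O", "S")) {
  if (!length(elements)) stop("elements must be non-empty")
  at <- atoms(structure)
  out <- lapply(elements, function(e) {
    sub <- structure
    atoms(sub) <- at[at$element == e, , drop = FALSE]
    sub
  })
  names(out) <- elements
  attr(out, "unassigned") <- at[!(at$element %in% elements), , drop = FALSE]
  out
}
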