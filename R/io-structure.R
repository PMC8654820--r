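#' Read a coordinate file (PDB or mmCIF)
#'
#' Atom records are parsed with \pkg{bio3d}; the unit cell is taken from the
#' CRYST1 record (PDB) or the `_cell` category (mmCIF). Coordinates are
#' orthogonal Angstrom. All alternate conformers are retained as read; use
#' [stripStructure()] to resolve them.
#'
#' @param path file path
#' @param dialect "pdb" or "mmcif"; default guesses from the extension
#' @param cell optional [UnitCell-class] supplied by the caller when the file
#'   carries none
#' @return an [XtalStructure-class]
#' @seealso [writeStructure()], [stripStructure()]
#' @export
readStructure <- function(path, dialect = c("auto", "pdb", "mmcif"),
                          cell = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  parsed <- tryCatch(
    if (dialect == "pdb")
      suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE,
                                       multi = FALSE))
    else
      suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e)
      stop("failed to parse ", dialect, " file '", path, "': ",
           conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  element <- at$elesy
  blank <- is.na(element) | element == ""
  element[blank] <- guessElement(at$elety[blank])
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    resname = at$resid,
    atom = at$elety,
    element = toupper(trimws(element)),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    hetero = at$type == "HETATM",
    stringsAsFactors = FALSE)
  filecell <- if (dialect == "pdb") readCryst1(path) else readCifCell(path)
  if (is.null(filecell)) filecell <- cell
  if (is.null(filecell))
    stop("no unit cell in '", path,
         "' (no CRYST1/_cell record); supply one via the 'cell' argument")
  sg <- attr(filecell, "spaceGroup") %||% "P 1"
  attr(filecell, "spaceGroup") <- NULL
  XtalStructure(atoms, cell = filecell, spaceGroup = sg)
}

guessElement <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(nm, 1, 2)
  known2 <- c("FE", "ZN", "MG", "MN", "SE", "CL", "BR", "NA", "CA")
  ifelse(two %in% known2 & nchar(nm) == 2, two, substr(nm, 1, 1))
}

readCryst1 <- function(path) {
  hdr <- readLines(path, n = 200L, warn = FALSE)
  ln <- grep("^CRYST1", hdr, value = TRUE)
  if (!length(ln)) return(NULL)
  ln <- ln[1]
  num <- function(i, j) as.numeric(substr(ln, i, j))
  cell <- UnitCell(num(7, 15), num(16, 24), num(25, 33),
                   num(34, 40), num(41, 47), num(48, 54))
  sg <- trimws(substr(ln, 56, 66))
  attr(cell, "spaceGroup") <- if (nzchar(sg)) sg else "P 1"
  cell
}

readCifCell <- function(path) {
  txt <- readLines(path, warn = FALSE)
  g <- function(tag) {
    ln <- grep(paste0("^_cell[._]", tag, "[[:space:]]"), txt, value = TRUE)
    if (!length(ln)) return(NA_real_)
    as.numeric(gsub(".*[[:space:]]([-0-9.]+).*", "\\1", ln[1]))
  }
  v <- c(g("length_a"), g("length_b"), g("length_c"),
         g("angle_alpha"), g("angle_beta"), g("angle_gamma"))
  if (anyNA(v)) return(NULL)
  cell <- UnitCell(v[1], v[2], v[3], v[4], v[5], v[6])
  sgl <- grep("^_symmetry[._]space_group_name_H-M", txt, value = TRUE)
  sg <- if (length(sgl))
    gsub("^[^'\"]*['\"](.*)['\"].*$", "\\1", sgl[1]) else "P 1"
  attr(cell, "spaceGroup") <- sg
  cell
}

#' Write a coordinate file
#'
#' PDB output goes through \pkg{bio3d}'s writer with a CRYST1 record
#' prepended; mmCIF output writes a minimal `atom_site` loop with the cell.
#' Both are re-readable by [readStructure()] at the format's native
#' precision (0.001 Angstrom for PDB coordinates).
#'
#' @param structure an [XtalStructure-class]
#' @param path output path
#' @param dialect "pdb" or "mmcif"; default guesses from the extension
#' @return `path`, invisibly
#' @export
writeStructure <- function(structure, path, dialect = c("auto", "pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  at <- atoms(structure)
  if (dialect == "pdb") {
    cryst <- if (!is.null(structure@cell))
      sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
              structure@cell@a, structure@cell@b, structure@cell@c,
              structure@cell@alpha, structure@cell@beta,
              structure@cell@gamma, structure@spaceGroup, 1L)
    else character()
    if (nrow(at)) {
      tmp <- tempfile(fileext = ".pdb")
      on.exit(unlink(tmp), add = TRUE)
      bio3d::write.pdb(file = tmp,
                       type = ifelse(at$hetero, "HETATM", "ATOM"),
                       xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                       resno = at$resno, resid = at$resname,
                       eleno = seq_len(nrow(at)), elety = at$atom,
                       chain = at$chain, o = at$occ, b = at$b,
                       alt = ifelse(at$altloc == "", NA, at$altloc),
                       elesy = at$element)
      body <- readLines(tmp, warn = FALSE)
    } else body <- "END"
    writeLines(c(cryst, body), path)
  } else {
    writeMmcif(structure, path)
  }
  invisible(path)
}

writeMmcif <- function(structure, path) {
  at <- atoms(structure)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("data_structure", con)
  if (!is.null(structure@cell)) {
    cl <- structure@cell
    writeLines(sprintf("_cell.length_a %.4f", cl@a), con)
    writeLines(sprintf("_cell.length_b %.4f", cl@b), con)
    writeLines(sprintf("_cell.length_c %.4f", cl@c), con)
    writeLines(sprintf("_cell.angle_alpha %.4f", cl@alpha), con)
    writeLines(sprintf("_cell.angle_beta %.4f", cl@beta), con)
    writeLines(sprintf("_cell.angle_gamma %.4f", cl@gamma), con)
    writeLines(sprintf("_symmetry.space_group_name_H-M '%s'",
                       structure@spaceGroup), con)
  }
  if (nrow(at)) {
    # full canonical PDBx column set: common parsers index these fields by
    # position, so a reduced loop is not portable
    writeLines(c("loop_", "_atom_site.group_PDB", "_atom_site.id",
                 "_atom_site.type_symbol", "_atom_site.label_atom_id",
                 "_atom_site.label_alt_id", "_atom_site.label_comp_id",
                 "_atom_site.label_asym_id", "_atom_site.label_entity_id",
                 "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
                 "_atom_site.Cartn_x", "_atom_site.Cartn_y",
                 "_atom_site.Cartn_z", "_atom_site.occupancy",
                 "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
                 "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
                 "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
                 "_atom_site.pdbx_PDB_model_num"), con)
    alt <- ifelse(at$altloc == "", ".", at$altloc)
    writeLines(sprintf(
      "%s %d %s %s %s %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
      ifelse(at$hetero, "HETATM", "ATOM"),
      seq_len(nrow(at)), at$element, at$atom, alt,
      at$resname, at$chain, at$resno,
      at$x, at$y, at$z, at$occ, at$b,
      at$resno, at$resname, at$chain, at$atom), con)
  }
  invisible(path)
}
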