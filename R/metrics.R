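#' Box correlation coefficient (bCC)
#'
#' Pearson correlation over all voxels of two equally shaped boxes, the
#' local-quality metric relating a high-resolution observed map to the
#' calculated density of the model under evaluation:
#' bCC = cov(rho_obs, rho_calc) / sqrt(var(rho_obs) * var(rho_calc)).
#' Invariant to affine rescaling of either box and to applying the same
#' cube rotation to both.
#'
#' A box with zero variance (empty or flat region) raises a condition of
#' class `"degenerateBoxError"` rather than returning a silent value,
#' because scoring empty solvent regions would corrupt training labels.
#'
#' @param boxObs,boxCalc [VoxelBox-class] objects or bare arrays of equal
#'   dimensions
#' @return correlation in \[-1, 1\]
#' @examples
#' b <- array(rnorm(8), c(2, 2, 2))
#' bcc(b, b)   # 1
#' @export
bcc <- function(boxObs, boxCalc) {
  a <- as.numeric(if (is(boxObs, "VoxelBox")) boxObs@values else boxObs)
  b <- as.numeric(if (is(boxCalc, "VoxelBox")) boxCalc@values else boxCalc)
  if (length(a) != length(b))
    stop("boxes differ in size: ", length(a), " vs ", length(b))
  va <- var(a); vb <- var(b)
  if (!is.finite(va) || !is.finite(vb) || va == 0 || vb == 0)
    stop(degenerateBoxError(
      sprintf("degenerate box: variance obs=%.3g calc=%.3g", va, vb)))
  cor(a, b)
}

degenerateBoxError <- function(msg) {
  structure(class = c("degenerateBoxError", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

cellsMatch <- function(c1, c2, tol = 1e-3) {
  p1 <- c(c1@a, c1@b, c1@c, c1@alpha, c1@beta, c1@gamma)
  p2 <- c(c2@a, c2@b, c2@c, c2@alpha, c2@beta, c2@gamma)
  all(abs(p1 - p2) <= tol * pmax(abs(p1), abs(p2)))
}

#' Per-residue bCC of a model against an observed map
#'
#' The standard scoring pipeline: strip waters (and optionally hetero
#' compounds) and hydrogens, resolve alternate conformers, reset all B
#' factors to `bFactor`, synthesize the calculated density over the cell,
#' then for every standard amino-acid residue extract the observed and
#' calculated boxes at the residue centroid and correlate them. Hetero
#' atoms retained with `dropHetero = FALSE` contribute to the calculated
#' density as environment but are not themselves scored.
#'
#' @param structure an [XtalStructure-class] (P1)
#' @param obsMap observed [DensityMap-class]; its cell must match the
#'   structure's to 0.1 percent
#' @param table a [ScatteringTable-class]
#' @param edge,spacing box geometry (Angstrom), defaults 12 and 0.5
#' @param bFactor uniform B reset value (Angstrom^2)
#' @param dropHetero remove non-water hetero compounds before synthesis
#' @param calcMap optional precomputed calculated map (skips synthesis)
#' @return data.frame (chain, resno, resname, bcc, flag); residues hitting a
#'   degenerate box get bcc = NA and flag = "degenerate"
#' @export
perResidueBcc <- function(structure, obsMap, table = scatteringTable(),
                          edge = 12.0, spacing = 0.5, bFactor = 2.0,
                          dropHetero = TRUE, calcMap = NULL) {
  cell <- requireP1Cell(structure)
  if (!cellsMatch(cell, obsMap@cell))
    stop("structure and map unit cells differ by more than 0.1%")
  model <- stripStructure(structure, dropWaters = TRUE,
                          dropHetero = dropHetero, dropHydrogens = TRUE)
  model <- setUniformBfactor(model, bFactor)
  if (is.null(calcMap))
    calcMap <- synthesizeMap(model, gridDimsForSpacing(cell, min(spacing, 0.5)),
                             table = table)
  res <- residueTable(model)
  res <- res[res$resname %in% STANDARD_AA & !res$hetero, , drop = FALSE]
  out <- data.frame(chain = res$chain, resno = res$resno,
                    resname = res$resname, bcc = NA_real_,
                    flag = "", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(res))) {
    ra <- residueAtoms(model, res$chain[i], res$resno[i])
    ctr <- residueCentroid(ra)
    sc <- tryCatch(
      bcc(extractBox(obsMap, ctr, edge, spacing),
          extractBox(calcMap, ctr, edge, spacing)),
      degenerateBoxError = function(e) NA_real_)
    out$bcc[i] <- sc
    if (is.na(sc)) out$flag[i] <- "degenerate"
  }
  out
}

#' Real-space correlation coefficient (RSCC), mask approximation
#'
#' Pearson correlation between observed and calculated maps restricted to
#' grid points within `maskRadius` of any non-hydrogen atom of the residue.
#' This is a documented approximation of the conventional atomic-footprint
#' RSCC (no per-atom weighting); unlike bCC it sees only the residue's own
#' footprint, so it stays high for a residue that fits a model-biased map
#' even when the surroundings are wrong.
#'
#' @param structure an [XtalStructure-class]
#' @param obsMap,calcMap [DensityMap-class] objects on the same grid
#' @param chain,resno residue selector
#' @param maskRadius mask radius in Angstrom (default 1.5)
#' @return correlation over the masked voxels
#' @export
rscc <- function(structure, obsMap, calcMap, chain, resno,
                 maskRadius = 1.5) {
  if (!identical(dim(obsMap@values), dim(calcMap@values)))
    stop("observed and calculated maps must share a grid")
  ra <- residueAtoms(structure, chain, resno)
  ra <- ra[!(ra$element %in% c("H", "D")), , drop = FALSE]
  if (!nrow(ra)) stop("residue ", chain, resno, " not found or hydrogen-only")
  d <- dim(obsMap@values)
  cell <- obsMap@cell
  msk <- cpp_mask_near_atoms(d[1], d[2], d[3], orthMatrix(cell),
                             fracMatrix(cell),
                             as.matrix(ra[, c("x", "y", "z")]), maskRadius)
  if (!any(msk)) stop("empty mask: no grid point within ", maskRadius,
                      " A of residue ", chain, resno)
  cor(as.numeric(obsMap@values)[msk], as.numeric(calcMap@values)[msk])
}

#' Ligand delta-bCC: bound vs unbound model against one observed map
#'
#' For every standard residue with any atom within `contactRadius` of a
#' ligand atom, computes bCC with the ligand included in the calculated
#' density (bound model) and without it (unbound model), against the same
#' observed map. A positive delta supports the bound interpretation.
#'
#' @param structureBound model containing the ligand (non-water HETATM)
#' @param structureUnbound same model without the ligand
#' @param obsMap observed [DensityMap-class]
#' @param contactRadius contact cutoff in Angstrom (default 5)
#' @param ... passed to [perResidueBcc()] (box geometry, table)
#' @return data.frame (chain, resno, resname, bccBound, bccUnbound, delta)
#' @export
ligandDeltaBcc <- function(structureBound, structureUnbound, obsMap,
                           contactRadius = 5.0, ...) {
  atb <- atoms(structureBound)
  lig <- atb[atb$hetero & !(atb$resname %in% WATER_RESNAMES), , drop = FALSE]
  if (!nrow(lig))
    stop("no ligand (non-water HETATM) found in the bound structure")
  prot <- atb[!atb$hetero, , drop = FALSE]
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  mind <- apply(pxyz, 1, function(p)
    sqrt(min(colSums((t(lxyz) - p)^2))))
  contact <- unique(prot[mind <= contactRadius, c("chain", "resno"),
                         drop = FALSE])
  bb <- perResidueBcc(structureBound, obsMap, dropHetero = FALSE, ...)
  bu <- perResidueBcc(structureUnbound, obsMap, dropHetero = FALSE, ...)
  key <- function(df) paste(df$chain, df$resno)
  sel <- key(bb) %in% key(contact)
  out <- bb[sel, c("chain", "resno", "resname", "bcc"), drop = FALSE]
  names(out)[4] <- "bccBound"
  out$bccUnbound <- bu$bcc[match(key(out), key(bu))]
  out$delta <- out$bccBound - out$bccUnbound
  rownames(out) <- NULL
  out
}

#' Fractional bCC contribution of a single atom
#'
#' Removes one atom from the calculated density only (the observed map is
#' untouched) and reports |bCC_with - bCC_without| / bCC_with for the given
#' residue's box. An atom outside the box contributes nothing (warning,
#' returns 0). In a 12 A box a single water oxygen contributes less than 1
#' percent, which is why water handling matters little for the metric at
#' that box size.
#'
#' @param structure an [XtalStructure-class]; the environment model
#' @param obsMap observed [DensityMap-class]
#' @param chain,resno the scored residue
#' @param atomSelector named list matched against the atom table (e.g.
#'   `list(chain = "A", resno = 101L, atom = "O")`); must select exactly
#'   one atom
#' @param edge,spacing box geometry
#' @param bFactor uniform B reset (Angstrom^2)
#' @param table a [ScatteringTable-class]
#' @param dropHetero passed to the scoring pipeline; keep FALSE when the
#'   selected atom is itself a hetero atom (e.g. a water oxygen)
#' @param dMinCalc when non-NULL, synthesize the calculated maps
#'   band-limited at this resolution (Fourier synthesis of structure
#'   factors) instead of by direct real-space summation. At B = 2 the
#'   atomic peaks are far sharper than a 0.5 A grid can represent, so
#'   direct sampling aliases; band-limiting at the grid Nyquist
#'   (2 x spacing) gives the conventional crystallographic calculated map
#' @return fractional change (>= 0)
#' @export
singleAtomContribution <- function(structure, obsMap, chain, resno,
                                   atomSelector, edge = 12.0, spacing = 0.5,
                                   bFactor = 2.0, table = scatteringTable(),
                                   dropHetero = FALSE, dMinCalc = NULL) {
  cell <- requireP1Cell(structure)
  model <- stripStructure(structure, dropWaters = FALSE,
                          dropHetero = dropHetero, dropHydrogens = TRUE)
  model <- setUniformBfactor(model, bFactor)
  at <- atoms(model)
  sel <- rep(TRUE, nrow(at))
  for (nm in names(atomSelector)) sel <- sel & at[[nm]] == atomSelector[[nm]]
  if (sum(sel) != 1)
    stop("atomSelector matched ", sum(sel), " atoms; need exactly 1")
  ctr <- residueCentroid(residueAtoms(model, chain, resno))
  pos <- as.numeric(at[sel, c("x", "y", "z")])
  if (any(abs(pos - ctr) > edge / 2)) {
    warning("selected atom lies outside the residue's box; contribution 0")
    return(0)
  }
  dims <- gridDimsForSpacing(cell, min(spacing, 0.5))
  synth <- if (is.null(dMinCalc)) {
    function(m) synthesizeMap(m, dims, table = table)
  } else {
    function(m) mapFromReflections(structureFactors(m, dMinCalc,
                                                    table = table),
                                   dims = dims)
  }
  full <- synth(model)
  solo <- model
  atoms(solo) <- at[sel, , drop = FALSE]
  soloMap <- synth(solo)
  without <- full
  without@values <- full@values - soloMap@values
  obox <- extractBox(obsMap, ctr, edge, spacing)
  bWith <- bcc(obox, extractBox(full, ctr, edge, spacing))
  bWithout <- bcc(obox, extractBox(without, ctr, edge, spacing))
  abs(bWith - bWithout) / abs(bWith)
}

#' Write a per-residue score table as TSV
#'
#' Fixed columns: chain, resnum, resname, score, flag.
#'
#' @param scores data.frame from [perResidueBcc()] (or with compatible
#'   columns; the score column is the first numeric column)
#' @param path output path
#' @param scoreName name recorded in the header comment
#' @return `path`, invisibly
#' @export
writeScoreTable <- function(scores, path, scoreName = "bCC") {
  sc <- data.frame(chain = scores$chain, resnum = scores$resno,
                   resname = scores$resname,
                   score = scores[[intersect(c("bcc", "score", "delta"),
                                             names(scores))[1]]],
                   flag = if (is.null(scores$flag)) "" else scores$flag)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# score: ", scoreName), con)
  suppressWarnings(write.table(sc, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' Store per-residue scores in the B-factor column
#'
#' Returns a copy of the structure whose atoms carry their residue's score
#' in the B column (missing scores become 0), for rainbow-by-B rendering in
#' standard viewers after [writeStructure()].
#'
#' @param structure an [XtalStructure-class]
#' @param scores data.frame with chain, resno and a score column (bcc)
#' @return the annotated structure
#' @export
bccAsBfactor <- function(structure, scores) {
  at <- atoms(structure)
  key <- paste(at$chain, at$resno)
  skey <- paste(scores$chain, scores$resno)
  scol <- intersect(c("bcc", "score"), names(scores))[1]
  val <- scores[[scol]][match(key, skey)]
  val[is.na(val)] <- 0
  at$b <- val
  atoms(structure) <- at
  structure
}
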