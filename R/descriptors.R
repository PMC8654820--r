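#' Build five-channel voxel descriptors
#'
#' Channel 1 is the observed map boxed at the residue centroid; channels
#' 2-5 are the calculated density of the model's C, N, O and S atoms
#' (B factors reset to `bFactor`, waters/hydrogens stripped), boxed on the
#' same lattice. `buildDescriptorSet` synthesizes the four element maps once
#' and extracts every requested residue; `buildDescriptors` is the
#' single-residue convenience wrapper.
#'
#' @param structure an [XtalStructure-class] (P1)
#' @param obsMap observed [DensityMap-class]
#' @param residues data.frame with chain and resno columns, or NULL for all
#'   standard amino-acid residues
#' @param table a [ScatteringTable-class]
#' @param edge,spacing box geometry (Angstrom)
#' @param bFactor uniform B reset (Angstrom^2)
#' @param dropHetero remove non-water hetero compounds before synthesis
#' @param structureId identifier stored in record metadata
#' @param resolutionTag resolution label stored in record metadata
#' @param elements element channels, fixed order (default C, N, O, S)
#' @return `buildDescriptorSet`: list of unlabeled
#'   [DescriptorRecord-class]; records whose observed-map box is degenerate
#'   carry `meta$flag = "degenerate"`
#' @export
buildDescriptorSet <- function(structure, obsMap, residues = NULL,
                               table = scatteringTable(), edge = 12.0,
                               spacing = 0.5, bFactor = 2.0,
                               dropHetero = TRUE, structureId = "",
                               resolutionTag = "",
                               elements = c("C", "N", "O", "S")) {
  cell <- requireP1Cell(structure)
  if (!cellsMatch(cell, obsMap@cell))
    stop("structure and map unit cells differ by more than 0.1%")
  model <- stripStructure(structure, dropWaters = TRUE,
                          dropHetero = dropHetero, dropHydrogens = TRUE)
  model <- setUniformBfactor(model, bFactor)
  dims <- gridDimsForSpacing(cell, min(spacing, 0.5))
  parts <- splitByElement(model, elements)
  emaps <- lapply(parts, function(p)
    if (nrow(atoms(p))) synthesizeMap(p, dims, table = table) else NULL)
  if (is.null(residues)) {
    residues <- residueTable(model)
    residues <- residues[residues$resname %in% STANDARD_AA & !residues$hetero,
                         , drop = FALSE]
  }
  n <- as.integer(round(edge / spacing))
  lapply(seq_len(nrow(residues)), function(i) {
    ra <- residueAtoms(model, residues$chain[i], residues$resno[i])
    ctr <- residueCentroid(ra)
    ch <- array(0, c(n, n, n, 5L))
    obox <- extractBox(obsMap, ctr, edge, spacing)
    ch[, , , 1] <- obox@values
    for (e in seq_along(elements))
      if (!is.null(emaps[[e]]))
        ch[, , , e + 1] <- extractBox(emaps[[e]], ctr, edge, spacing)@values
    flag <- if (var(as.numeric(obox@values)) == 0) "degenerate" else ""
    DescriptorRecord(ch, NA_real_, meta = list(
      aa = ra$resname[1], chain = as.character(residues$chain[i]),
      resno = as.integer(residues$resno[i]), structureId = structureId,
      resolutionTag = resolutionTag, flag = flag,
      center = ctr, edge = edge, spacing = spacing))
  })
}

#' @rdname buildDescriptorSet
#' @param chain,resno residue selector for the single-residue wrapper
#' @param ... further arguments passed to `buildDescriptorSet`
#' @export
buildDescriptors <- function(structure, obsMap, chain, resno, ...) {
  recs <- buildDescriptorSet(structure, obsMap,
                             residues = data.frame(chain = chain,
                                                   resno = resno), ...)
  recs[[1]]
}

#' Label a descriptor record with bCC_act
#'
#' The label is the bCC between the correct structure's observed map (boxed
#' on the record's lattice) and the record's all-element calculated density,
#' i.e. the sum of its element channels. A degenerate box leaves the record
#' unlabeled with `meta$flag = "degenerate"`.
#'
#' @param record a [DescriptorRecord-class] carrying box geometry metadata
#' @param correctObsMap the correct (high-resolution) observed
#'   [DensityMap-class]
#' @return the record with `label` set (or NA + flag when degenerate)
#' @export
labelRecord <- function(record, correctObsMap) {
  m <- record@meta
  if (is.null(m$center))
    stop("record lacks box-geometry metadata (center/edge/spacing)")
  obox <- extractBox(correctObsMap, m$center, m$edge, m$spacing)
  calc <- record@channels[, , , 2] + record@channels[, , , 3] +
    record@channels[, , , 4] + record@channels[, , , 5]
  lab <- tryCatch(bcc(obox@values, calc),
                  degenerateBoxError = function(e) NA_real_)
  record@label <- lab
  if (is.na(lab)) record@meta$flag <- "degenerate"
  record
}

#' Balance a labeled record set by label histogram
#'
#' Labels are histogrammed over \[0, 1\] into `nBins` equal bins; each bin is
#' downsampled uniformly at random to at most `perBinCap` records and the
#' output order is shuffled, all deterministically under `seed`. An
#' unbiased label distribution matters for regression performance, so this
#' is applied before training. Unlabeled records are dropped.
#'
#' @param records list of [DescriptorRecord-class]
#' @param nBins number of histogram bins (>= 2)
#' @param perBinCap maximum records kept per bin
#' @param seed integer RNG seed
#' @return balanced, shuffled list of records
#' @export
balanceDataset <- function(records, nBins = 10L, perBinCap = Inf, seed = 1L) {
  if (nBins < 2) stop("nBins must be >= 2")
  labs <- vapply(records, function(r) r@label, numeric(1))
  keep <- which(!is.na(labs))
  bins <- pmin(pmax(floor(labs[keep] * nBins), 0), nBins - 1L)
  withSeed(seed, {
    sel <- unlist(lapply(split(keep, bins), function(idx) {
      if (length(idx) > perBinCap) sample(idx, perBinCap) else idx
    }), use.names = FALSE)
    records[sample(sel)]
  })
}

#' All 24 rotated copies of a descriptor record
#'
#' Applies each cube rotation jointly to all five channels; labels are
#' invariant (bCC of a jointly rotated pair is unchanged) and voxel
#' multisets are preserved.
#'
#' @param record a [DescriptorRecord-class]
#' @return list of 24 records (index 1 is the unrotated input)
#' @export
augmentRotations <- function(record) {
  lapply(0:23, function(k) rotateRecord(record, k))
}

rotateRecord <- function(record, k) {
  if (k == 0) return(record)
  ch <- record@channels
  for (c in 1:5) ch[, , , c] <- rotateBox(record@channels[, , , c], k)
  record@channels <- ch
  record
}

#' Compare predicted and actual bCC tables
#'
#' Joins the two tables on residue keys (structureId, chain, resno when
#' present) and summarizes agreement.
#'
#' @param predTable data.frame with a `bccPred` column and key columns
#' @param actTable data.frame with a `bcc` (or `bccAct`) column and the same
#'   keys
#' @return list: `r` (Pearson), `meanDelta` (mean bccPred - bccAct),
#'   `sdDelta`, `n`, `perAA` (data.frame breakdown when an `aa`/`resname`
#'   column is present), `unmatched` (keys present on one side only)
#' @export
evaluatePredictions <- function(predTable, actTable) {
  keys <- intersect(c("structureId", "resolutionTag", "chain", "resno"),
                    intersect(names(predTable), names(actTable)))
  if (!length(keys)) stop("no shared key columns")
  kp <- do.call(paste, c(predTable[keys], sep = "\r"))
  ka <- do.call(paste, c(actTable[keys], sep = "\r"))
  act <- actTable[[intersect(c("bccAct", "bcc"), names(actTable))[1]]]
  m <- match(kp, ka)
  ok <- !is.na(m)
  pred <- predTable$bccPred[ok]
  actm <- act[m[ok]]
  fin <- is.finite(pred) & is.finite(actm)
  pred <- pred[fin]; actm <- actm[fin]
  if (!length(pred)) stop("empty join between prediction and actual tables")
  delta <- pred - actm
  aaCol <- intersect(c("aa", "resname"), names(predTable))
  perAA <- NULL
  if (length(aaCol)) {
    aa <- predTable[[aaCol[1]]][ok][fin]
    perAA <- do.call(rbind, lapply(split(seq_along(pred), aa), function(i)
      data.frame(aa = aa[i[1]], n = length(i),
                 r = if (length(i) > 2) cor(pred[i], actm[i]) else NA_real_,
                 meanDelta = mean(delta[i]))))
    rownames(perAA) <- NULL
  }
  list(r = if (length(pred) > 1) cor(pred, actm) else NA_real_,
       meanDelta = mean(delta), sdDelta = sd(delta), n = length(pred),
       perAA = perAA,
       unmatched = sum(!ok) + sum(!(ka %in% kp)))
}
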