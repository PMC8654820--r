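#' Write a descriptor archive
#'
#' A directory holding one serialized chunk per amino-acid type plus
#' `manifest.json` with per-type counts, the label histogram over \[0, 1\],
#' generator provenance (config and seeds as supplied) and content hashes.
#' Re-reading yields bit-identical channels.
#'
#' @param records list of [DescriptorRecord-class]
#' @param path archive directory (created; must not already contain a
#'   manifest unless `overwrite`)
#' @param provenance list stored verbatim in the manifest (generator
#'   parameters, seeds)
#' @param overwrite replace an existing archive
#' @return a [DescriptorArchive-class]
#' @export
writeArchive <- function(records, path, provenance = list(),
                         overwrite = FALSE) {
  mf <- file.path(path, "manifest.json")
  if (file.exists(mf) && !overwrite)
    stop("archive already exists at ", path, " (use overwrite = TRUE)")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  aa <- vapply(records, function(r) r@meta$aa %||% "UNK", character(1))
  chunks <- split(records, aa)
  files <- character(0)
  for (type in names(chunks)) {
    f <- file.path(path, paste0("records-", type, ".rds"))
    saveRDS(chunks[[type]], f, version = 2)
    files <- c(files, f)
  }
  labs <- vapply(records, function(r) r@label, numeric(1))
  hist <- table(cut(labs[!is.na(labs)], breaks = seq(0, 1, by = 0.1),
                    include.lowest = TRUE))
  manifest <- list(
    counts = lapply(chunks, length),
    nRecords = length(records),
    nLabeled = sum(!is.na(labs)),
    labelHistogram = as.list(setNames(as.integer(hist), names(hist))),
    provenance = provenance,
    chunkMd5 = as.list(setNames(unname(tools::md5sum(files)),
                                basename(files))))
  manifest$hash <- manifestHash(manifest)
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  new("DescriptorArchive", path = path, manifest = manifest)
}

manifestHash <- function(manifest) {
  manifest$hash <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Open a descriptor archive
#'
#' Verifies manifest counts against the stored chunks.
#'
#' @param path archive directory
#' @return a [DescriptorArchive-class]
#' @export
readArchive <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  arch <- new("DescriptorArchive", path = path, manifest = manifest)
  for (type in names(manifest$counts)) {
    n <- length(readRecords(arch, type))
    if (n != manifest$counts[[type]])
      stop("manifest count mismatch for ", type, ": manifest says ",
           manifest$counts[[type]], ", chunk holds ", n)
  }
  arch
}

#' Read records from an archive
#'
#' @param archive a [DescriptorArchive-class]
#' @param aminoAcid three-letter type, or NULL for all types
#' @return list of [DescriptorRecord-class]
#' @export
readRecords <- function(archive, aminoAcid = NULL) {
  types <- if (is.null(aminoAcid)) names(archive@manifest$counts)
           else aminoAcid
  out <- list()
  for (type in types) {
    f <- file.path(archive@path, paste0("records-", type, ".rds"))
    if (!file.exists(f)) stop("missing chunk for ", type)
    out <- c(out, readRDS(f))
  }
  out
}

#' Amino-acid types stored in an archive
#' @param archive a [DescriptorArchive-class]
#' @export
archiveTypes <- function(archive) names(archive@manifest$counts)
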