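#' Read a CCP4/MRC density map (mode 2)
#'
#' Only mode-2 (float32) maps covering exactly one unit cell are supported.
#' The file's fast/medium/slow axis permutation (MAPC/MAPR/MAPS) is
#' normalized on read so that internal storage is always a, b, c with a
#' fastest.
#'
#' @param path file path
#' @param provenance label stored on the returned map
#' @return a [DensityMap-class]
#' @seealso [writeMap()]
#' @export
readMap <- function(path, provenance = "observed") {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  hdr <- readBin(con, "integer", n = 10, size = 4, endian = endian)
  if (hdr[4] < 0 || hdr[4] > 16) {
    # wrong endianness; reopen big-endian
    close(con)
    con <- file(path, "rb")
    endian <- "big"
    hdr <- readBin(con, "integer", n = 10, size = 4, endian = endian)
  }
  nc <- hdr[1]; nr <- hdr[2]; ns <- hdr[3]; mode <- hdr[4]
  starts <- hdr[5:7]; mx <- hdr[8:10]
  if (mode != 2)
    stop("unsupported CCP4/MRC mode ", mode, " (only mode 2, float32)")
  cellpar <- readBin(con, "numeric", n = 6, size = 4, endian = endian)
  maporder <- readBin(con, "integer", n = 3, size = 4, endian = endian)
  readBin(con, "numeric", n = 3, size = 4, endian = endian)  # min/max/mean
  ispg <- readBin(con, "integer", n = 1, size = 4, endian = endian)
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = endian)
  readBin(con, "raw", n = 1024 - 4 * 24)   # rest of the 256-word header
  if (nsymbt > 0) readBin(con, "raw", n = nsymbt)
  if (!setequal(maporder, 1:3))
    stop("inconsistent header: MAPC/MAPR/MAPS = ",
         paste(maporder, collapse = ","))
  ncrs <- c(nc, nr, ns)
  if (any(ncrs < 1) || any(mx < 1))
    stop("inconsistent header dimensions")
  if (any(ncrs != mx[maporder]) || any(starts != 0))
    stop("map does not cover exactly one unit cell ",
         "(expected starts 0 and column counts equal to cell sampling)")
  vals <- readBin(con, "numeric", n = prod(ncrs), size = 4, endian = endian)
  if (length(vals) != prod(ncrs)) stop("truncated map data")
  arr <- array(vals, dim = ncrs)
  arr <- aperm(arr, match(1:3, maporder))
  cell <- UnitCell(cellpar[1], cellpar[2], cellpar[3],
                   cellpar[4], cellpar[5], cellpar[6])
  DensityMap(arr, cell, provenance = provenance)
}

#' Write a CCP4/MRC density map (mode 2)
#'
#' Always writes canonical axis order (a fastest, then b, then c), start
#' indices 0 and full-cell sampling. Values are stored as float32.
#'
#' @param map a [DensityMap-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeMap <- function(map, path) {
  stopifnot(is(map, "DensityMap"))
  d <- dim(map@values)
  cl <- map@cell
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wInt(d)                       # NC NR NS
  wInt(2L)                      # MODE
  wInt(c(0L, 0L, 0L))           # starts
  wInt(d)                       # sampling of full cell
  wFlt(c(cl@a, cl@b, cl@c, cl@alpha, cl@beta, cl@gamma))
  wInt(1:3)                     # MAPC MAPR MAPS
  v <- map@values
  wFlt(c(min(v), max(v), mean(v)))
  wInt(1L)                      # ISPG (P1)
  wInt(0L)                      # NSYMBT
  wInt(rep(0L, 25))             # extra (words 25-49)
  wFlt(c(0, 0, 0))              # ORIGIN (words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  wFlt(sd(as.numeric(v)))
  wInt(0L)                      # NLABL
  writeBin(raw(800), con)       # label block
  wFlt(as.numeric(v))
  invisible(path)
}
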