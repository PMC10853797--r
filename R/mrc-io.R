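#' Read an MRC/CCP4 2014 density map
#'
#' Parses the 1024-byte header and mode-2 (float32) voxel data. The axis
#' permutation declared by \code{mapc/mapr/maps} is normalized so the
#' returned grid is always in X, Y, Z order; the origin is taken from the
#' \code{origin} header words when set, otherwise from
#' \code{nxstart/nystart/nzstart}; per-axis voxel spacing is
#' \code{cella/mx,my,mz}. On-disk Angstroms are converted to nm.
#'
#' @param path Path to an MRC/CCP4 file.
#' @return A \code{\link{density_grid}}.
#' @export
read_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ints1 <- readBin(con, "integer", 10L, size = 4L, endian = "little")
  if (any(!is.finite(ints1)) || length(ints1) < 10L)
    stop("MRC format error: truncated header (nx/ny/nz block)",
         call. = FALSE)
  nx <- ints1[1]; ny <- ints1[2]; nz <- ints1[3]; mode <- ints1[4]
  nstart <- ints1[5:7]; mxyz <- ints1[8:10]
  cella <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  readBin(con, "numeric", 3L, size = 4L, endian = "little")  # cellb
  mapcrs <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  readBin(con, "numeric", 3L, size = 4L, endian = "little")  # dmin/max/mean
  readBin(con, "integer", 2L, size = 4L, endian = "little")  # ispg, nsymbt
  readBin(con, "raw", 100L)                                  # extra
  orig <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  map_id <- readChar(con, 4L, useBytes = TRUE)
  readBin(con, "raw", 4L)                                    # machst
  readBin(con, "numeric", 1L, size = 4L, endian = "little")  # rms
  readBin(con, "integer", 1L, size = 4L, endian = "little")  # nlabl
  readBin(con, "raw", 800L)                                  # labels
  if (!identical(substr(map_id, 1, 3), "MAP"))
    stop("MRC format error: missing 'MAP ' identifier (word 53)",
         call. = FALSE)
  if (mode != 2L)
    stop(sprintf("MRC format error: unsupported mode %d (only mode 2 float32)",
                 mode), call. = FALSE)
  if (nx < 1L || ny < 1L || nz < 1L)
    stop("MRC format error: non-positive dimension in nx/ny/nz",
         call. = FALSE)
  if (!all(sort(mapcrs) == 1:3))
    stop("MRC format error: mapc/mapr/maps must be a permutation of 1,2,3",
         call. = FALSE)
  if (any(mxyz < 1L) || any(cella <= 0))
    stop("MRC format error: invalid cell (cella/mx,my,mz)", call. = FALSE)
  nvox <- as.numeric(nx) * ny * nz
  raw_vals <- readBin(con, "numeric", nvox, size = 4L, endian = "little")
  if (length(raw_vals) != nvox)
    stop("MRC format error: truncated data block", call. = FALSE)
  raw_arr <- array(raw_vals, c(nx, ny, nz))
  # disk dimension d holds crystal axis mapcrs[d]; reorder to X,Y,Z
  perm <- match(1:3, mapcrs)
  vals <- aperm(raw_arr, perm)
  spacing_A <- cella / mxyz               # per crystal axis X,Y,Z
  if (any(abs(orig) > 0)) {
    origin_A <- orig
  } else {
    # nstart is in disk (column/row/section) order; map to crystal axes
    origin_A <- nstart[perm] * spacing_A
  }
  density_grid(vals, origin = origin_A / 10, spacing = spacing_A / 10)
}

#' Write a density grid as MRC/CCP4 2014
#'
#' Writes mode-2 (float32) voxel data in canonical X, Y, Z axis order with
#' the origin stored in the \code{origin} header words (\code{nstart} = 0).
#' Lengths are converted nm to Angstrom.
#'
#' @param grid A \code{\link{density_grid}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_map <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  d <- grid$dims
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  vals <- as.numeric(grid$values)
  wi(c(d, 2L))                       # nx ny nz mode
  wi(c(0L, 0L, 0L))                  # nxstart nystart nzstart
  wi(d)                              # mx my mz
  wf(grid$spacing * d * 10)          # cella, Angstrom
  wf(c(90, 90, 90))                  # cellb
  wi(1:3)                            # mapc mapr maps
  wf(c(min(vals), max(vals), mean(vals)))
  wi(c(1L, 0L))                      # ispg, nsymbt
  writeBin(raw(100L), con)           # extra
  wf(grid$origin * 10)               # origin, Angstrom
  writeChar("MAP ", con, 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(vals))                # rms
  wi(1L)                             # nlabl
  lab <- charToRaw(sprintf("%-80s", "dnaspool synthetic/processed map"))
  writeBin(c(lab, raw(720L)), con)
  writeBin(vals, con, size = 4L, endian = "little")
  invisible(path)
}
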