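# Minimal LAS 1.2 reader/writer. The pipeline consumes geometry and the
# classification byte only, so point formats 0-3 are accepted on read
# (extra attributes are skipped via the record stride) and format 0 is
# written. Coordinates are stored quantized at the usual 1 mm scale.

LAS_HEADER_SIZE <- 227L
LAS_SCALE <- 0.001

#' Write a point cloud as a LAS file
#'
#' Writes LAS 1.2, point data format 0, with x/y/z quantized at 1 mm and
#' the per-point classification codes preserved.
#'
#' @param cloud a [PointCloud3D-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCloudLAS <- function(cloud, path) {
  n <- length(cloud)
  if (n == 0) stop("refusing to write an empty cloud")
  off <- c(min(cloud@x), min(cloud@y), min(cloud@z))
  xi <- as.integer(round((cloud@x - off[1]) / LAS_SCALE))
  yi <- as.integer(round((cloud@y - off[2]) / LAS_SCALE))
  zi <- as.integer(round((cloud@z - off[3]) / LAS_SCALE))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("LASF", con, 4, eos = NULL)
  writeBin(c(0L, 0L), con, size = 2)              # source id, encoding
  writeBin(raw(16), con)                          # GUID
  writeBin(as.raw(c(1L, 2L)), con)                # version 1.2
  sysid <- charToRaw(formatC("canopy3d", width = -32))
  writeBin(sysid[1:32], con)
  soft <- charToRaw(formatC("canopy3d R package", width = -64))
  writeBin(soft[1:32], con)
  writeBin(c(1L, 2026L), con, size = 2)           # day, year
  writeBin(LAS_HEADER_SIZE, con, size = 2)        # header size
  writeBin(LAS_HEADER_SIZE, con, size = 4)        # offset to points
  writeBin(0L, con, size = 4)                     # number of VLRs
  writeBin(as.raw(0L), con)                       # point format 0
  writeBin(20L, con, size = 2)                    # record length
  writeBin(n, con, size = 4)                      # point count
  writeBin(rep(0L, 5), con, size = 4)             # points by return
  writeBin(rep(LAS_SCALE, 3), con, size = 8)      # scales
  writeBin(off, con, size = 8)                    # offsets
  writeBin(c(max(cloud@x), min(cloud@x), max(cloud@y), min(cloud@y),
             max(cloud@z), min(cloud@z)), con, size = 8)

  rec <- matrix(as.raw(0), nrow = 20, ncol = n)
  rec[1:4, ] <- matrix(writeBin(xi, raw(), size = 4), nrow = 4)
  rec[5:8, ] <- matrix(writeBin(yi, raw(), size = 4), nrow = 4)
  rec[9:12, ] <- matrix(writeBin(zi, raw(), size = 4), nrow = 4)
  rec[15, ] <- as.raw(0x11)                       # return 1 of 1
  rec[16, ] <- as.raw(cloud@classification)
  writeBin(as.vector(rec), con)
  invisible(path)
}

#' Read a point cloud from a LAS file
#'
#' Accepts LAS point data formats 0-3; only x, y, z and classification are
#' consumed. A truncated point block is an error, not a silent partial
#' read, and an empty cloud is flagged.
#'
#' @param path LAS file path.
#' @return A [PointCloud3D-class].
#' @export
readCloudLAS <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.info(path)$size
  if (sz < LAS_HEADER_SIZE) stop("malformed LAS: file shorter than header")
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "LASF")) stop("malformed LAS: bad signature")
  invisible(readBin(con, raw(), 20))              # ids, GUID
  ver <- readBin(con, integer(), 2, size = 1)
  invisible(readBin(con, raw(), 64 + 4))          # sys id, software, dates
  header_size <- readBin(con, integer(), 1, size = 2)
  point_offset <- readBin(con, integer(), 1, size = 4)
  invisible(readBin(con, integer(), 1, size = 4)) # VLR count
  fmt <- as.integer(readBin(con, raw(), 1))
  reclen <- readBin(con, integer(), 1, size = 2)
  npts <- readBin(con, integer(), 1, size = 4)
  if (!fmt %in% 0:3) stop("unsupported LAS point format: ", fmt)
  if (npts == 0) stop("empty LAS point cloud")
  invisible(readBin(con, integer(), 5, size = 4))
  scales <- readBin(con, numeric(), 3, size = 8)
  offs <- readBin(con, numeric(), 3, size = 8)
  if (sz < point_offset + as.numeric(npts) * reclen)
    stop("malformed LAS: truncated point data")
  seek(con, point_offset)
  blob <- readBin(con, raw(), npts * reclen)
  if (length(blob) < npts * reclen)
    stop("malformed LAS: truncated point data")

  base <- rep((0:(npts - 1)) * reclen, each = 4)
  int_at <- function(o) {
    readBin(blob[base + o + rep(1:4, npts)], integer(), npts, size = 4)
  }
  x <- int_at(0L) * scales[1] + offs[1]
  y <- int_at(4L) * scales[2] + offs[2]
  z <- int_at(8L) * scales[3] + offs[3]
  cls <- as.integer(blob[(0:(npts - 1)) * reclen + 16L])
  PointCloud3D(x, y, z, cls)
}

#' Read ROI markers from a 4-row CSV
#'
#' The CSV must carry columns \code{x} and \code{y} (geo meters) with rows
#' in the canonical order upper-left, upper-right, lower-left, lower-right.
#'
#' @param path CSV path.
#' @return A [RoiMarkers-class].
#' @export
readRoiMarkers <- function(path) {
  d <- utils::read.csv(path)
  if (nrow(d) != 4 || !all(c("x", "y") %in% names(d)))
    stop("ROI marker file must have 4 rows with columns x, y")
  RoiMarkers(cbind(d$x, d$y))
}

#' Clip a point cloud to a region of interest
#'
#' Returns exactly the points inside the marker quadrilateral, boundary
#' inclusive, so that the clip and its complement partition the cloud.
#'
#' @param cloud a [PointCloud3D-class].
#' @param markers a [RoiMarkers-class].
#' @param complement return the points outside instead.
#' @return A [PointCloud3D-class].
#' @export
clipRoi <- function(cloud, markers, complement = FALSE) {
  stopifnot(is(markers, "RoiMarkers"))
  # polygon in ring order UL, UR, LR, LL
  poly <- markers@corners[c(1, 2, 4, 3), , drop = FALSE]
  inside <- pointInPolygon(cloud@x, cloud@y, poly)
  if (!complement && !any(inside))
    warning("no points inside the ROI markers")
  cloudSubset(cloud, if (complement) !inside else inside)
}

# even-odd point-in-polygon, boundary inclusive
pointInPolygon <- function(px, py, poly, tol = 1e-9) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  onEdge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    # boundary: distance from point to segment <= tol
    dx <- xj - xi; dy <- yj - yi
    L2 <- dx * dx + dy * dy
    t <- if (L2 > 0) pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / L2))
         else 0
    ex <- xi + t * dx - px
    ey <- yi + t * dy - py
    onEdge <- onEdge | (ex * ex + ey * ey <= tol * tol)
    j <- i
  }
  inside | onEdge
}

#' Convert geo coordinates to (continuous) pixel coordinates
#'
#' Linear map with pixel column/row 0 starting at the origin (the raster's
#' upper-left corner); rows increase southwards. The origin maps to pixel
#' (0, 0) and a point 1 m east of the origin at 1 cm/pixel maps to column
#' 100. Integer cell indices are the floor of the continuous coordinates;
#' mapping a cell index back through [pixelToGeo] returns the cell center,
#' within half a pixel of any geo point in the cell.
#'
#' @param coord numeric length-2 (x, y) or n x 2 matrix, geo meters.
#' @param origin geo (x, y) of the raster upper-left corner.
#' @param resolution cm per pixel (> 0).
#' @return matrix with columns \code{col}, \code{row} (continuous pixels).
#' @export
geoToPixel <- function(coord, origin, resolution) {
  if (resolution <= 0) stop("resolution must be > 0")
  if (is.null(dim(coord))) coord <- matrix(coord, ncol = 2)
  res_m <- resolution / 100
  cbind(col = (coord[, 1] - origin[1]) / res_m,
        row = (origin[2] - coord[, 2]) / res_m)
}

#' @rdname geoToPixel
#' @param pixel (col, row) continuous pixel coordinates or cell indices;
#'   with \code{center = TRUE}, integer cell indices are mapped to their
#'   cell-center geo position.
#' @param center map cell indices to cell centers.
#' @export
pixelToGeo <- function(pixel, origin, resolution, center = FALSE) {
  if (resolution <= 0) stop("resolution must be > 0")
  if (is.null(dim(pixel))) pixel <- matrix(pixel, ncol = 2)
  res_m <- resolution / 100
  shift <- if (center) 0.5 else 0
  cbind(x = origin[1] + (pixel[, 1] + shift) * res_m,
        y = origin[2] - (pixel[, 2] + shift) * res_m)
}
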