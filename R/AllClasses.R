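#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib canopy3d, .registration = TRUE
NULL

# LAS classification codes used throughout the package
LAS_UNCLASSIFIED <- 0L
LAS_GROUND <- 2L
LAS_VEGETATION <- 5L
LAS_NOISE <- 7L

#' PointCloud3D: a 3D point cloud with per-point classification
#'
#' The raw substrate of the pipeline: parallel coordinate vectors in metric
#' geo-coordinates (z up) plus an optional per-point LAS classification code
#' (0 = unclassified, 2 = ground, 5 = above-ground vegetation, 7 = noise).
#' After terrain normalization the z unit switches from meters to
#' centimeters above the locally interpolated ground surface, recorded in
#' the \code{zUnit} slot; ground points then carry z = 0 exactly.
#'
#' @slot x,y,z numeric coordinate vectors of equal length.
#' @slot classification integer LAS class codes, same length.
#' @slot zUnit `"m"` for geo elevations, `"cm"` for normalized heights.
#' @export
setClass("PointCloud3D",
  representation(x = "numeric", y = "numeric", z = "numeric",
                 classification = "integer", zUnit = "character"),
  prototype(x = numeric(0), y = numeric(0), z = numeric(0),
            classification = integer(0), zUnit = "m"),
  validity = function(object) {
    n <- length(object@x)
    if (length(object@y) != n || length(object@z) != n)
      return("x, y, z must have equal length")
    if (length(object@classification) != n)
      return("classification must match coordinate length")
    if (n > 0 && (anyNA(object@x) || anyNA(object@y) || anyNA(object@z) ||
                  any(!is.finite(object@x)) || any(!is.finite(object@y)) ||
                  any(!is.finite(object@z))))
      return("coordinates must be finite")
    if (length(object@zUnit) != 1 || !object@zUnit %in% c("m", "cm"))
      return("zUnit must be \"m\" or \"cm\"")
    TRUE
  })

#' Construct a PointCloud3D
#'
#' @param x,y,z numeric coordinates (meters; z in cm once normalized).
#' @param classification integer LAS codes; defaults to unclassified.
#' @param zUnit `"m"` or `"cm"`.
#' @return A [PointCloud3D-class] object.
#' @export
PointCloud3D <- function(x, y, z, classification = NULL, zUnit = "m") {
  n <- length(x)
  if (is.null(classification)) classification <- rep(LAS_UNCLASSIFIED, n)
  new("PointCloud3D", x = as.numeric(x), y = as.numeric(y),
      z = as.numeric(z), classification = as.integer(classification),
      zUnit = zUnit)
}

#' @describeIn PointCloud3D-class number of points
#' @param x a PointCloud3D
#' @export
setMethod("length", "PointCloud3D", function(x) length(x@x))

setMethod("show", "PointCloud3D", function(object) {
  cat("PointCloud3D with", length(object), "points (z unit:",
      object@zUnit, ")\n")
  if (length(object) > 0) {
    cat(sprintf("  x: [%.3f, %.3f]  y: [%.3f, %.3f]  z: [%.3f, %.3f]\n",
                min(object@x), max(object@x), min(object@y), max(object@y),
                min(object@z), max(object@z)))
    tab <- table(object@classification)
    cat("  classification:",
        paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  }
})

#' Coordinates of a point cloud as a matrix
#' @param cloud a [PointCloud3D-class]
#' @return n x 3 numeric matrix with columns x, y, z.
#' @export
cloudCoords <- function(cloud) {
  cbind(x = cloud@x, y = cloud@y, z = cloud@z)
}

#' Per-point LAS classification codes
#' @param cloud a [PointCloud3D-class]
#' @export
cloudClassification <- function(cloud) cloud@classification

#' Subset a point cloud by index
#' @param cloud a [PointCloud3D-class]
#' @param i logical or integer index
#' @export
cloudSubset <- function(cloud, i) {
  new("PointCloud3D", x = cloud@x[i], y = cloud@y[i], z = cloud@z[i],
      classification = cloud@classification[i], zUnit = cloud@zUnit)
}

#' Ground / above-ground views of a classified cloud
#' @param cloud a [PointCloud3D-class]
#' @export
groundPoints <- function(cloud) {
  cloudSubset(cloud, cloud@classification == LAS_GROUND)
}

#' @rdname groundPoints
#' @export
aboveGroundPoints <- function(cloud) {
  cloudSubset(cloud, cloud@classification == LAS_VEGETATION)
}

#' CHMRaster: a gridded canopy height model
#'
#' Heights in centimeters on a regular grid at \code{resolution} cm per
#' pixel. Row 1 is the northern (max-y) edge; \code{origin} holds the geo
#' coordinates (meters) of the top-left raster corner, so the center of
#' cell (r, c) sits at \code{origin + ((c - 0.5) res, -(r - 0.5) res)} (res
#' in meters). Cells without data are NA.
#'
#' @slot heights numeric matrix of canopy heights (cm), NA = no data.
#' @slot resolution cm per pixel (> 0).
#' @slot origin numeric(2): geo x, y of the top-left corner (meters).
#' @export
setClass("CHMRaster",
  representation(heights = "matrix", resolution = "numeric",
                 origin = "numeric"),
  validity = function(object) {
    if (length(object@resolution) != 1 || object@resolution <= 0)
      return("resolution must be a single positive value (cm per pixel)")
    if (length(object@origin) != 2)
      return("origin must be geo (x, y) of the top-left corner")
    h <- object@heights[!is.na(object@heights)]
    if (length(h) && min(h) < -1e-9)
      return("heights must be >= 0 where present")
    TRUE
  })

#' @describeIn CHMRaster-class grid dimensions (rows, cols)
#' @param x a CHMRaster
#' @export
setMethod("dim", "CHMRaster", function(x) dim(x@heights))

setMethod("show", "CHMRaster", function(object) {
  d <- dim(object@heights)
  cat(sprintf("CHMRaster %d x %d @ %g cm/px, origin (%.3f, %.3f)\n",
              d[1], d[2], object@resolution, object@origin[1],
              object@origin[2]))
  v <- object@heights[!is.na(object@heights)]
  if (length(v))
    cat(sprintf("  data cells: %d (%.1f%%), height range [%.1f, %.1f] cm\n",
                length(v), 100 * length(v) / prod(d), min(v), max(v)))
})

#' Height matrix of a CHM raster
#' @param chm a [CHMRaster-class]
#' @export
chmHeights <- function(chm) chm@heights

#' Resolution (cm per pixel) of a CHM raster
#' @param chm a [CHMRaster-class]
#' @export
chmResolution <- function(chm) chm@resolution

#' Geo origin (top-left corner, meters) of a CHM raster
#' @param chm a [CHMRaster-class]
#' @export
chmOrigin <- function(chm) chm@origin

#' RoiMarkers: four region-of-interest corner coordinates
#'
#' Geo coordinates of the region of interest in the fixed order upper-left,
#' upper-right, lower-left, lower-right ("upper" = larger y / northern
#' edge). The quadrilateral must have positive area.
#'
#' @slot corners 4 x 2 numeric matrix (x, y) in the canonical order.
#' @export
setClass("RoiMarkers",
  representation(corners = "matrix"),
  validity = function(object) {
    m <- object@corners
    if (!is.numeric(m) || nrow(m) != 4 || ncol(m) != 2)
      return("corners must be a 4 x 2 numeric matrix")
    if (anyNA(m)) return("corner coordinates must be finite")
    # polygon order UL, UR, LR, LL; shoelace area must be non-degenerate
    p <- m[c(1, 2, 4, 3), , drop = FALSE]
    a <- 0.5 * sum(p[, 1] * p[c(2:4, 1), 2] - p[c(2:4, 1), 1] * p[, 2])
    if (abs(a) < 1e-12) return("markers form a degenerate quadrilateral")
    TRUE
  })

#' Construct RoiMarkers
#' @param corners 4 x 2 matrix of geo (x, y), rows ordered upper-left,
#'   upper-right, lower-left, lower-right.
#' @export
RoiMarkers <- function(corners) {
  new("RoiMarkers", corners = as.matrix(corners))
}

setMethod("show", "RoiMarkers", function(object) {
  cat("RoiMarkers (UL, UR, LL, LR):\n")
  print(object@corners)
})

#' CanopyCurve: a Gaussian-fitted canopy structural curve
#'
#' Frequency/amplitude samples taken along the diagonal of a plot CHM's
#' centered DFT log-magnitude, the Gaussian least-squares fit through them,
#' and the derived scalars: trapezoidal area under the fitted curve (AUC),
#' apex curvature, and (once a cohort is normalized) the 3D canopy index.
#'
#' @slot x frequency sample positions.
#' @slot raw sampled amplitudes (0-255 grayscale of the spectrogram).
#' @slot fitted Gaussian-fitted amplitudes (equals raw when the fit failed).
#' @slot A,mu,sigma Gaussian parameters (NA when the fit failed).
#' @slot fitOk logical fit-success flag.
#' @slot auc trapezoidal area under the curve.
#' @slot curvature curvature at the curve apex.
#' @slot dci normalized 3D canopy index (NA until cohort normalization).
#' @export
setClass("CanopyCurve",
  representation(x = "numeric", raw = "numeric", fitted = "numeric",
                 A = "numeric", mu = "numeric", sigma = "numeric",
                 fitOk = "logical", auc = "numeric", curvature = "numeric",
                 dci = "numeric"),
  prototype(A = NA_real_, mu = NA_real_, sigma = NA_real_, fitOk = FALSE,
            auc = NA_real_, curvature = NA_real_, dci = NA_real_),
  validity = function(object) {
    if (length(object@raw) != length(object@x))
      return("raw amplitudes must match frequency samples")
    if (length(object@fitted) != length(object@x))
      return("fitted amplitudes must match frequency samples")
    if (isTRUE(object@fitOk) && !is.na(object@sigma) && object@sigma <= 0)
      return("sigma must be > 0 on a successful fit")
    TRUE
  })

setMethod("show", "CanopyCurve", function(object) {
  cat(sprintf(
    "CanopyCurve: %d samples on [%g, %g]; fit %s", length(object@x),
    min(object@x), max(object@x), if (object@fitOk) "ok" else "FAILED"))
  if (object@fitOk)
    cat(sprintf(" (A=%.3g, mu=%.3g, sigma=%.3g)", object@A, object@mu,
                object@sigma))
  cat("\n")
  if (!is.na(object@auc)) cat(sprintf("  auc=%.4g", object@auc))
  if (!is.na(object@curvature)) cat(sprintf("  curvature=%.4g",
                                            object@curvature))
  if (!is.na(object@dci)) cat(sprintf("  3DCI=%.4f", object@dci))
  cat("\n")
})

#' PlotGrid: per-plot rectangular masks with row/column identity
#'
#' One record per field plot: the bounding rectangle detected by plot
#' segmentation and the refined (entropy-recentered) sampling rectangle,
#' both in 1-based inclusive pixel coordinates of the segmented CHM image.
#'
#' @slot plots data.frame with columns row_id, col_id, x0, y0, x1, y1,
#'   rx0, ry0, rx1, ry1, refined_flag.
#' @slot resolution cm per pixel of the segmented image.
#' @slot origin geo (x, y) of the image top-left corner.
#' @export
setClass("PlotGrid",
  representation(plots = "data.frame", resolution = "numeric",
                 origin = "numeric"),
  validity = function(object) {
    need <- c("row_id", "col_id", "x0", "y0", "x1", "y1")
    if (!all(need %in% names(object@plots)))
      return(paste("plots must contain", paste(need, collapse = ", ")))
    p <- object@plots
    if (nrow(p) && any(p$x1 < p$x0 | p$y1 < p$y0))
      return("degenerate plot rectangles")
    TRUE
  })

#' @describeIn PlotGrid-class number of plots
#' @param x a PlotGrid
#' @export
setMethod("length", "PlotGrid", function(x) nrow(x@plots))

setMethod("show", "PlotGrid", function(object) {
  cat(sprintf("PlotGrid with %d plots (%d rows x %d cols)\n",
              nrow(object@plots),
              length(unique(object@plots$row_id)),
              length(unique(object@plots$col_id))))
})

#' Plot records of a PlotGrid as a data.frame
#' @param grid a [PlotGrid-class]
#' @export
plotRecords <- function(grid) grid@plots
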