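#' Statistical outlier removal
#'
#' For every point the mean distance to its \code{n_neighbors} nearest
#' neighbours is computed; a point is an outlier when that mean exceeds
#' \code{avg + k * std}, where \code{avg} and \code{std} are the mean and
#' standard deviation of the per-point means over the whole cloud.
#'
#' @param cloud a [PointCloud3D-class] with more than \code{n_neighbors}
#'   points.
#' @param n_neighbors neighbour count (default 50).
#' @param k standard-deviation multiplier (default 1).
#' @return list with \code{clean} and \code{outliers} (disjoint
#'   [PointCloud3D-class]s; outliers carry LAS class 7).
#' @export
denoiseCloud <- function(cloud, n_neighbors = 50, k = 1) {
  n <- length(cloud)
  if (n_neighbors < 1) stop("n_neighbors must be >= 1")
  if (k <= 0) stop("k must be > 0")
  if (n <= n_neighbors)
    stop("cloud must contain more than n_neighbors points")
  d <- .knn_mean_dist(cloud@x, cloud@y, cloud@z, as.integer(n_neighbors))
  flag <- d > mean(d) + k * stats::sd(d)
  out <- cloudSubset(cloud, flag)
  out@classification <- rep(LAS_NOISE, length(out))
  list(clean = cloudSubset(cloud, !flag), outliers = out)
}

#' Classify ground and above-ground points
#'
#' Local lowest-point seeding on a coarse grid (cell size = \code{radius}
#' meters) followed by region growing: starting from the lowest seed,
#' neighbouring cell seeds are accepted while the implied slope stays
#' below \code{max_slope_deg} (plus the \code{height_threshold}
#' allowance); rejected cells (e.g. fully canopy-covered ones) get their
#' ground level interpolated from accepted neighbours. A point is ground
#' when it sits within \code{height_threshold} cm of the bilinearly
#' interpolated ground surface.
#'
#' @param cloud a denoised [PointCloud3D-class].
#' @param radius coarse-grid cell size in meters (default 2).
#' @param max_slope_deg maximum terrain slope for region growing.
#' @param height_threshold ground band above the local surface, cm.
#' @return The cloud with classification 2 (ground) / 5 (above-ground).
#' @export
classifyGround <- function(cloud, radius = 2, max_slope_deg = 15,
                           height_threshold = 10) {
  if (length(cloud) == 0) stop("empty cloud")
  if (radius <= 0) stop("radius must be > 0")
  g <- groundGridEstimate(cloud, cell = radius,
                          max_slope_deg = max_slope_deg,
                          height_threshold = height_threshold,
                          stat = "min")
  surf <- bilinearGrid(g, cloud@x, cloud@y)
  ground <- (cloud@z - surf) <= height_threshold / 100
  cloud@classification <- ifelse(ground, LAS_GROUND, LAS_VEGETATION)
  cloud@classification <- as.integer(cloud@classification)
  cloud
}

# Coarse-grid ground surface estimate.
# stat = "min": per-cell lowest z (seeding); stat = "mean": per-cell mean
# (used on already-classified ground points for normalization).
groundGridEstimate <- function(cloud, cell, max_slope_deg = 15,
                               height_threshold = 10, stat = c("min", "mean"),
                               grow = TRUE) {
  stat <- match.arg(stat)
  x0 <- min(cloud@x); y0 <- min(cloud@y)
  nx <- max(1L, ceiling((max(cloud@x) - x0) / cell))
  ny <- max(1L, ceiling((max(cloud@y) - y0) / cell))
  ix <- pmin(nx - 1L, pmax(0L, as.integer(floor((cloud@x - x0) / cell))))
  iy <- pmin(ny - 1L, pmax(0L, as.integer(floor((cloud@y - y0) / cell))))
  id <- ix * ny + iy + 1L
  G <- matrix(NA_real_, nrow = ny, ncol = nx)
  v <- if (stat == "min") tapply(cloud@z, id, min) else tapply(cloud@z, id, mean)
  G[as.integer(names(v))] <- v

  if (grow && stat == "min" && sum(!is.na(G)) > 1) {
    tol <- tan(max_slope_deg * pi / 180) * cell * sqrt(2) +
      height_threshold / 100
    acc <- matrix(FALSE, ny, nx)
    filled <- which(!is.na(G))
    acc[filled[which.min(G[filled])]] <- TRUE
    repeat {
      accN <- neighborStat(ifelse(acc, G, NA), "mean")
      newly <- !acc & !is.na(G) & !is.na(accN) & abs(G - accN) <= tol
      if (!any(newly)) break
      acc[newly] <- TRUE
    }
    G[!acc] <- NA   # canopy-dominated cells: re-interpolate below
  }
  # fill empty cells by iterative neighbour averaging
  while (anyNA(G)) {
    fill <- neighborStat(G, "mean")
    isna <- is.na(G)
    G[isna] <- fill[isna]
    if (all(is.na(G))) stop("no usable ground cells")
  }
  list(G = G, x0 = x0, y0 = y0, cell = cell, nx = nx, ny = ny)
}

# mean of available 8-neighbours, NA where none
neighborStat <- function(G, stat = "mean") {
  ny <- nrow(G); nx <- ncol(G)
  s <- matrix(0, ny, nx); cnt <- matrix(0, ny, nx)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(ny, ny + dr)
    cs <- max(1, 1 + dc):min(nx, nx + dc)
    src <- G[rs - dr, cs - dc, drop = FALSE]
    ok <- !is.na(src)
    s[rs, cs][ok] <- s[rs, cs][ok] + src[ok]
    cnt[rs, cs][ok] <- cnt[rs, cs][ok] + 1
  }
  out <- s / cnt
  out[cnt == 0] <- NA
  out
}

# bilinear sample of a cell-centred coarse grid at point coordinates
bilinearGrid <- function(g, px, py) {
  fx <- (px - g$x0) / g$cell - 0.5
  fy <- (py - g$y0) / g$cell - 0.5
  cx <- pmin(pmax(fx, 0), g$nx - 1)
  cy <- pmin(pmax(fy, 0), g$ny - 1)
  c0 <- pmin(g$nx - 1L, pmax(0L, as.integer(floor(cx))))
  r0 <- pmin(g$ny - 1L, pmax(0L, as.integer(floor(cy))))
  c1 <- pmin(c0 + 1L, g$nx - 1L)
  r1 <- pmin(r0 + 1L, g$ny - 1L)
  wx <- cx - c0; wy <- cy - r0
  v00 <- g$G[cbind(r0 + 1L, c0 + 1L)]
  v01 <- g$G[cbind(r0 + 1L, c1 + 1L)]
  v10 <- g$G[cbind(r1 + 1L, c0 + 1L)]
  v11 <- g$G[cbind(r1 + 1L, c1 + 1L)]
  (1 - wy) * ((1 - wx) * v00 + wx * v01) + wy * ((1 - wx) * v10 + wx * v11)
}

#' Flatten the terrain of a classified cloud
#'
#' Interpolates a ground surface from the ground-classified points (cell
#' means on a fine grid, bilinearly sampled), assigns ground points z = 0
#' exactly, and converts each above-ground point's z to its vertical
#' distance above the local ground surface, in centimeters. Idempotent:
#' a cloud already in normalized (cm) units is left unchanged apart from
#' re-zeroing ground points.
#'
#' @param cloud a [PointCloud3D-class] labeled by [classifyGround].
#' @param cell ground-surface grid cell size, meters.
#' @return The normalized [PointCloud3D-class] (zUnit "cm").
#' @export
normalizeHeights <- function(cloud, cell = 0.25) {
  isGround <- cloud@classification == LAS_GROUND
  if (!any(isGround)) stop("no ground points found")
  gcloud <- cloudSubset(cloud, isGround)
  g <- groundGridEstimate(gcloud, cell = cell, stat = "mean", grow = FALSE)
  surf <- bilinearGrid(g, cloud@x, cloud@y)
  scale <- if (cloud@zUnit == "m") 100 else 1
  z <- (cloud@z - surf) * scale
  z[isGround] <- 0
  cloud@z <- z
  cloud@zUnit <- "cm"
  cloud
}

#' TIN interpolation of scattered points onto a raster
#'
#' Piecewise-linear interpolation over the Delaunay triangulation of the
#' points, evaluated at raster cell centers; cells outside the convex
#' hull (or inside triangles longer than \code{max_edge}, when set) are
#' no-data.
#'
#' @param x,y point coordinates, meters (or a [PointCloud3D-class] as
#'   \code{x}).
#' @param z values to interpolate.
#' @param resolution cm per pixel.
#' @param max_edge skip triangles with an edge longer than this many
#'   meters (0 disables the cap).
#' @param bbox optional c(x0, y0, x1, y1) raster extent (defaults to the
#'   point bounding box).
#' @return list: \code{values} matrix (row 1 = north), \code{origin} geo
#'   (x, y) of the top-left corner, \code{resolution}.
#' @export
tinInterpolate <- function(x, y = NULL, z = NULL, resolution = 1,
                           max_edge = 0, bbox = NULL) {
  if (is(x, "PointCloud3D")) { y <- x@y; z <- x@z; x <- x@x }
  if (length(x) < 3) stop("need at least 3 points")
  keep <- !duplicated(round(cbind(x, y) / 1e-9))
  xs <- x[keep]; ys <- y[keep]; zs <- z[keep]
  if (length(xs) < 3 || isCollinear(xs, ys))
    stop("degenerate input: points are collinear")
  if (is.null(bbox)) bbox <- c(min(x), min(y), max(x), max(y))
  res_m <- resolution / 100
  ncol <- max(1L, ceiling((bbox[3] - bbox[1]) / res_m))
  nrow <- max(1L, ceiling((bbox[4] - bbox[2]) / res_m))
  origin <- c(bbox[1], bbox[2] + nrow * res_m)
  cx <- mean(range(xs)); cy <- mean(range(ys))
  vals <- .tin_rasterize(xs - cx, ys - cy, zs, as.integer(nrow),
                         as.integer(ncol), origin[1] - cx, origin[2] - cy,
                         res_m, max_edge)
  list(values = vals, origin = origin, resolution = resolution)
}

isCollinear <- function(x, y, tol = 1e-12) {
  if (length(x) < 3) return(TRUE)
  x0 <- x - mean(x); y0 <- y - mean(y)
  M <- cbind(x0, y0)
  s <- svd(crossprod(M))$d
  s[2] <= tol * max(s[1], 1)
}

#' Delaunay triangulation of 2D points
#'
#' @param x,y point coordinates.
#' @return integer matrix, one CCW triangle (vertex indices) per row.
#' @export
delaunayTriangles <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 points")
  cx <- mean(range(x)); cy <- mean(range(y))
  .delaunay_triangles(x - cx, y - cy)
}
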