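# Per-plot trait analysis: top-decile height, canopy coverage, alpha-shape
# 3D surface area, and voxel occupancy indices.

#' Plot-level crop height from the highest points
#'
#' Sorts the plot's height values descending and averages the top
#' \code{ceiling(fraction * n)} of them (the H10 rule at the default
#' fraction); ties at the cutoff are resolved deterministically by index.
#'
#' @param z height values, cm (normalized).
#' @param fraction top fraction to average (default 0.10).
#' @return plot height, cm.
#' @export
plotHeight <- function(z, fraction = 0.10) {
  n <- length(z)
  if (n == 0) stop("empty plot")
  m <- max(1L, ceiling(fraction * n))
  mean(sort(z, decreasing = TRUE, method = "radix")[seq_len(m)])
}

#' Canopy coverage of a plot footprint
#'
#' Retains the highest \code{fraction} of the plot's points, projects
#' them overhead onto a grid at \code{resolution} cm per pixel, and
#' applies an adaptive local threshold: the occupancy image is box-mean
#' filtered at \code{window} pixels and thresholded at half the median
#' filtered level over occupied cells (a box filter of a region indicator
#' crosses half its interior level at the region boundary, so within-crop
#' gaps close without inflating the outline). Coverage is the masked
#' fraction of the footprint.
#'
#' @param x,y point coordinates, meters.
#' @param z normalized heights, cm.
#' @param rect plot footprint c(x0, y0, x1, y1), geo meters.
#' @param fraction highest fraction of points kept (default 0.50).
#' @param resolution cm per pixel of the projection (default 1).
#' @param window adaptive-threshold window, pixels.
#' @return coverage in \[0, 1\]; attribute \code{"flag"} is
#'   \code{"empty"} for a pointless plot.
#' @export
canopyCoverage <- function(x, y, z, rect, fraction = 0.50, resolution = 1,
                           window = 51) {
  if (length(x) == 0) {
    out <- 0
    attr(out, "flag") <- "empty"
    return(out)
  }
  m <- max(1L, ceiling(fraction * length(z)))
  keep <- order(z, decreasing = TRUE)[seq_len(m)]
  res_m <- resolution / 100
  nx <- max(1L, ceiling((rect[3] - rect[1]) / res_m))
  ny <- max(1L, ceiling((rect[4] - rect[2]) / res_m))
  ix <- pmin(nx - 1L, pmax(0L, floor((x[keep] - rect[1]) / res_m)))
  iy <- pmin(ny - 1L, pmax(0L, floor((y[keep] - rect[2]) / res_m)))
  O <- matrix(0, ny, nx)
  O[unique(ix * ny + iy) + 1L] <- 1
  L <- boxMean(O, half = window %/% 2)
  thr <- 0.5 * stats::median(L[O > 0])
  cov <- mean(L >= thr)
  attr(cov, "flag") <- "ok"
  cov
}

#' 3D canopy surface area via voxel down-sampling and an alpha shape
#'
#' Points are packaged into a 3D grid at \code{voxel_size}, down-sampled
#' to one representative (the centroid of its points) per
#' \code{downsample_size} cell so within-canopy gaps are covered, and
#' meshed with a 3D alpha shape (Delaunay tetrahedra of circumradius at
#' most \code{alpha}); the trait is the total triangle area of the mesh
#' boundary. A flat canopy yields a thin closed slab, so its area counts
#' both faces (about twice the footprint).
#'
#' @param x,y point coordinates, meters.
#' @param z normalized heights, cm.
#' @param voxel_size,downsample_size,alpha voxel grid, down-sampling cell
#'   and alpha radius, cm (defaults 5, 5, 2 * voxel_size).
#' @return surface area, m2; NA with attribute \code{"flag"} =
#'   \code{"too_few_voxels"} when fewer than 4 representatives exist.
#' @export
surfaceArea3d <- function(x, y, z, voxel_size = 5, downsample_size = 5,
                          alpha = 2 * voxel_size) {
  stopifnot(voxel_size > 0, downsample_size > 0, alpha > 0)
  zm <- z / 100
  reps <- voxelCentroids(x, y, zm, voxel_size / 100)
  if (downsample_size > voxel_size)
    reps <- voxelCentroids(reps$x, reps$y, reps$z, downsample_size / 100)
  n <- length(reps$x)
  if (n < 4) {
    out <- NA_real_
    attr(out, "flag") <- "too_few_voxels"
    return(out)
  }
  # a height-constant canopy is a planar sheet: its alpha tetrahedra are
  # all degenerate slivers, so mesh it as a two-sided surface instead
  if (diff(range(reps$z)) < 1e-6) {
    tri <- delaunayTriangles(reps$x, reps$y)
    a <- sum(vapply(seq_len(nrow(tri)), function(t) {
      v <- tri[t, ]
      abs((reps$x[v[2]] - reps$x[v[1]]) * (reps$y[v[3]] - reps$y[v[1]]) -
          (reps$y[v[2]] - reps$y[v[1]]) * (reps$x[v[3]] - reps$x[v[1]])) / 2
    }, numeric(1)))
    return(2 * a)
  }
  # deterministic sub-micron jitter keeps gridded/coplanar inputs out of
  # degenerate tetrahedralizations; area effect is negligible
  j <- function(i, mult) (((i * mult) %% 9973) / 9973 - 0.5) * 1e-6
  i <- seq_len(n)
  .alpha_shape_area(reps$x + j(i, 7919), reps$y + j(i, 104729),
                    reps$z + j(i, 1299709), alpha / 100)
}

voxelCentroids <- function(x, y, z, s) {
  ix <- floor(x / s); iy <- floor(y / s); iz <- floor(z / s)
  id <- paste(ix, iy, iz)
  list(x = as.numeric(tapply(x, id, mean)),
       y = as.numeric(tapply(y, id, mean)),
       z = as.numeric(tapply(z, id, mean)))
}

#' Voxel occupancy indices (3DVI and 3DPI)
#'
#' Occupancy is binary per voxel, so both indices are invariant to
#' uniform point-density changes. The voxel index is occupied voxels over
#' total voxels in the plot bounding volume; the profile index sums, over
#' height bins one voxel tall, the occupied-cell fraction within each
#' bin.
#'
#' @param x,y point coordinates, meters.
#' @param z normalized heights, cm.
#' @param voxel_size voxel edge, cm (default 5).
#' @param bounds optional list(x =, y =, z =) of c(min, max) bounding
#'   volume (meters; z in cm); defaults to the point bounding box.
#' @return list: \code{vi_3d} in \[0, 1\], \code{pi_3d} dimensionless.
#' @export
voxelIndices <- function(x, y, z, voxel_size = 5, bounds = NULL) {
  if (length(x) == 0) stop("empty plot")
  s <- voxel_size / 100
  zm <- z / 100
  if (is.null(bounds))
    bounds <- list(x = range(x), y = range(y), z = range(zm))
  else if (!is.null(bounds$z_cm)) bounds$z <- bounds$z_cm / 100
  nx <- max(1L, ceiling((bounds$x[2] - bounds$x[1]) / s))
  ny <- max(1L, ceiling((bounds$y[2] - bounds$y[1]) / s))
  nz <- max(1L, ceiling((bounds$z[2] - bounds$z[1]) / s))
  ix <- pmin(nx - 1L, pmax(0L, floor((x - bounds$x[1]) / s)))
  iy <- pmin(ny - 1L, pmax(0L, floor((y - bounds$y[1]) / s)))
  iz <- pmin(nz - 1L, pmax(0L, floor((zm - bounds$z[1]) / s)))
  occ <- unique(cbind(ix, iy, iz))
  vi <- nrow(occ) / (as.numeric(nx) * ny * nz)
  perBin <- tabulate(occ[, 3] + 1L, nbins = nz)
  pi3d <- sum(perBin / (as.numeric(nx) * ny))
  list(vi_3d = vi, pi_3d = pi3d)
}

#' Compute the per-plot trait table
#'
#' Clips the normalized cloud to each plot's refined sampling rectangle
#' and computes the full trait record; the normalized surface index is
#' each plot's raw area over the cohort maximum of the run.
#'
#' @param cloud normalized [PointCloud3D-class] (zUnit cm).
#' @param grid a [PlotGrid-class].
#' @param height_fraction,coverage_fraction top fractions for the height
#'   and coverage traits.
#' @param voxel_size,downsample_size,alpha voxel parameters, cm.
#' @param resolution coverage projection resolution, cm per pixel.
#' @param use_refined sample from the refined rectangles (default) or the
#'   full bounding rectangles.
#' @return data.frame, one row per plot: ids, height_h10, coverage,
#'   surface_area_raw, surface_index, vi_3d, pi_3d, point_count, flag.
#' @export
computeTraits <- function(cloud, grid, height_fraction = 0.10,
                          coverage_fraction = 0.50, voxel_size = 5,
                          downsample_size = 5, alpha = 2 * voxel_size,
                          resolution = 1, use_refined = TRUE) {
  stopifnot(is(grid, "PlotGrid"))
  if (cloud@zUnit != "cm") stop("cloud must be normalized (zUnit cm)")
  p <- grid@plots
  ag <- aboveGroundPoints(cloud)
  rows <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    px <- if (use_refined) c(p$rx0[i], p$ry0[i], p$rx1[i], p$ry1[i])
          else c(p$x0[i], p$y0[i], p$x1[i], p$y1[i])
    # pixel rect (1-based inclusive) -> geo rect; +/- bounds of the cells
    tl <- pixelToGeo(c(px[1] - 1, px[2] - 1), grid@origin, grid@resolution)
    br <- pixelToGeo(c(px[3], px[4]), grid@origin, grid@resolution)
    rect <- c(tl[1], br[2], br[1], tl[2])
    sel <- ag@x >= rect[1] & ag@x <= rect[3] &
           ag@y >= rect[2] & ag@y <= rect[4]
    xs <- ag@x[sel]; ys <- ag@y[sel]; zs <- ag@z[sel]
    flag <- character(0)
    if (length(zs) == 0) {
      rows[[i]] <- data.frame(
        row_id = p$row_id[i], col_id = p$col_id[i],
        height_h10 = NA_real_, coverage = 0, surface_area_raw = NA_real_,
        surface_index = NA_real_, vi_3d = NA_real_, pi_3d = NA_real_,
        point_count = 0L, flag = "empty")
      next
    }
    h <- plotHeight(zs, height_fraction)
    cov <- canopyCoverage(xs, ys, zs, rect, coverage_fraction, resolution)
    sa <- surfaceArea3d(xs, ys, zs, voxel_size, downsample_size, alpha)
    if (!is.null(attr(sa, "flag"))) flag <- c(flag, attr(sa, "flag"))
    vx <- voxelIndices(xs, ys, zs, voxel_size)
    rows[[i]] <- data.frame(
      row_id = p$row_id[i], col_id = p$col_id[i], height_h10 = h,
      coverage = as.numeric(cov), surface_area_raw = as.numeric(sa),
      surface_index = NA_real_, vi_3d = vx$vi_3d, pi_3d = vx$pi_3d,
      point_count = length(zs),
      flag = if (length(flag)) paste(flag, collapse = ";") else "ok")
  }
  out <- do.call(rbind, rows)
  mx <- suppressWarnings(max(out$surface_area_raw, na.rm = TRUE))
  if (is.finite(mx) && mx > 0)
    out$surface_index <- out$surface_area_raw / mx
  out
}
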