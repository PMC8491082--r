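#' FieldLayout: geometry of a rectangular trial block
#'
#' Plot grid geometry of a drilled cereal trial: plots of
#' \code{plot_length} x \code{plot_width} meters arranged in
#' \code{n_plot_rows} x \code{n_plot_cols} with \code{inter_plot_gap}
#' meters of bare ground between them, each plot drilled with
#' \code{drill_rows_per_plot} rows of plants at \code{drill_row_spacing}
#' meters. Defaults mirror a wheat nitrogen trial: 2 x 3 m plots, 6 drill
#' rows at 0.15 m, 0.30 m gaps.
#'
#' @slot n_plot_rows,n_plot_cols plot grid counts (>= 1).
#' @slot plot_width,plot_length plot extent in meters (width = north-south).
#' @slot inter_plot_gap bare gap between plots, meters.
#' @slot drill_rows_per_plot,drill_row_spacing within-plot drilling.
#' @export
setClass("FieldLayout",
  representation(n_plot_rows = "numeric", n_plot_cols = "numeric",
                 plot_width = "numeric", plot_length = "numeric",
                 inter_plot_gap = "numeric", drill_rows_per_plot = "numeric",
                 drill_row_spacing = "numeric"),
  validity = function(object) {
    dims <- c(object@plot_width, object@plot_length, object@inter_plot_gap,
              object@drill_row_spacing)
    if (any(dims <= 0)) return("all dimensions must be > 0")
    cnts <- c(object@n_plot_rows, object@n_plot_cols,
              object@drill_rows_per_plot)
    if (any(cnts < 1) || any(cnts != round(cnts)))
      return("counts must be integers >= 1")
    TRUE
  })

#' @rdname FieldLayout-class
#' @param n_plot_rows,n_plot_cols,plot_width,plot_length,inter_plot_gap,drill_rows_per_plot,drill_row_spacing see slots.
#' @export
fieldLayout <- function(n_plot_rows = 9, n_plot_cols = 18, plot_width = 2,
                        plot_length = 3, inter_plot_gap = 0.3,
                        drill_rows_per_plot = 6, drill_row_spacing = 0.15) {
  new("FieldLayout", n_plot_rows = n_plot_rows, n_plot_cols = n_plot_cols,
      plot_width = plot_width, plot_length = plot_length,
      inter_plot_gap = inter_plot_gap,
      drill_rows_per_plot = drill_rows_per_plot,
      drill_row_spacing = drill_row_spacing)
}

#' CanopySpec: per-plot canopy parameters for the synthetic generator
#'
#' @slot mean_height mean plant height, cm (>= 0).
#' @slot height_sd spike-scale height texture, cm (per-point Gaussian
#'   jitter; the single variance dial the structural-index tests turn).
#' @slot coverage_fraction fraction (0-1) of the plot length carrying crop.
#' @slot point_density canopy returns per square meter of covered area.
#' @export
setClass("CanopySpec",
  representation(mean_height = "numeric", height_sd = "numeric",
                 coverage_fraction = "numeric", point_density = "numeric"),
  validity = function(object) {
    if (object@mean_height < 0) return("mean_height must be >= 0")
    if (object@height_sd < 0) return("height_sd must be >= 0")
    if (object@coverage_fraction < 0 || object@coverage_fraction > 1)
      return("coverage_fraction must be in [0, 1]")
    if (object@point_density <= 0) return("point_density must be > 0")
    TRUE
  })

#' @rdname CanopySpec-class
#' @param mean_height,height_sd,coverage_fraction,point_density see slots.
#' @export
canopySpec <- function(mean_height = 80, height_sd = 3,
                       coverage_fraction = 1, point_density = 200) {
  new("CanopySpec", mean_height = mean_height, height_sd = height_sd,
      coverage_fraction = coverage_fraction, point_density = point_density)
}

#' TerrainSpec: terrain model for the synthetic generator
#'
#' @slot slope_x,slope_y dimensionless gradients of the ground plane.
#' @slot ground_roughness_sd per-point ground elevation noise, cm (>= 0).
#' @slot base_elevation plane elevation at the field origin, meters.
#' @export
setClass("TerrainSpec",
  representation(slope_x = "numeric", slope_y = "numeric",
                 ground_roughness_sd = "numeric", base_elevation = "numeric"),
  validity = function(object) {
    if (object@ground_roughness_sd < 0) return("roughness must be >= 0")
    TRUE
  })

#' @rdname TerrainSpec-class
#' @param slope_x,slope_y,ground_roughness_sd,base_elevation see slots.
#' @export
terrainSpec <- function(slope_x = 0, slope_y = 0, ground_roughness_sd = 0.5,
                        base_elevation = 10) {
  new("TerrainSpec", slope_x = slope_x, slope_y = slope_y,
      ground_roughness_sd = ground_roughness_sd,
      base_elevation = base_elevation)
}

# deterministic ground plane (no roughness term)
terrainZ <- function(terrain, x, y) {
  terrain@base_elevation + terrain@slope_x * x + terrain@slope_y * y
}

# geo rectangle of plot (r, c): x0/x1 west-east, y0/y1 south-north.
# Plot row 1 is the northern row; field origin (0, 0) is the lower-left
# (south-west) corner of plot (n_plot_rows, 1).
plotRect <- function(layout, r, c) {
  pitch_x <- layout@plot_length + layout@inter_plot_gap
  pitch_y <- layout@plot_width + layout@inter_plot_gap
  x0 <- (c - 1) * pitch_x
  y1 <- layout@n_plot_rows * pitch_y - layout@inter_plot_gap -
    (r - 1) * pitch_y
  c(x0 = x0, y0 = y1 - layout@plot_width, x1 = x0 + layout@plot_length,
    y1 = y1)
}

# field bounding box including a one-gap-wide bare border
fieldExtent <- function(layout, border = layout@inter_plot_gap) {
  w <- layout@n_plot_cols * (layout@plot_length + layout@inter_plot_gap) -
    layout@inter_plot_gap
  h <- layout@n_plot_rows * (layout@plot_width + layout@inter_plot_gap) -
    layout@inter_plot_gap
  c(x0 = -border, y0 = -border, x1 = w + border, y1 = h + border)
}

#' Generate a synthetic field point cloud with known ground truth
#'
#' Builds a labeled point cloud emulating a LiDAR scan of a drilled trial
#' block: ground returns scattered over the whole extent on a sloped,
#' optionally rough terrain, and canopy returns placed along the drill
#' rows of each plot (Gaussian scatter around the row centerlines, so the
#' rasterized canopy carries the stripe periodicity a spectral analysis
#' detects), at terrain elevation plus a per-point plant height
#' \code{mean_height + N(0, height_sd)}. The returned ground truth is
#' recomputed from the generated points themselves: mean and top-decile
#' plant height per plot, and canopy coverage as 2-cm grid occupancy of
#' the plot footprint.
#'
#' @param layout a [FieldLayout-class].
#' @param canopy a single [CanopySpec-class] (recycled) or a list with one
#'   spec per plot in row-major order (row 1 = northern row).
#' @param terrain a [TerrainSpec-class].
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param ground_density ground returns per square meter over the full
#'   extent (gaps and plots alike).
#' @param row_scatter_sd cross-row scatter of canopy points, meters.
#' @param row_fraction fraction of canopy returns concentrated on the
#'   drill rows; the remainder models inter-row canopy closure, spread
#'   uniformly over the plot width.
#' @return list with \code{cloud} (a [PointCloud3D-class], classes 2 =
#'   ground / 5 = canopy) and \code{truth} (data.frame: plot_row,
#'   plot_col, x0, y0, x1, y1, true_mean_height_cm, true_h10_cm,
#'   true_coverage, n_canopy_points).
#' @export
generateField <- function(layout, canopy = canopySpec(),
                          terrain = terrainSpec(), seed = 1,
                          ground_density = 100, row_scatter_sd = 0.03,
                          row_fraction = 0.35) {
  nplots <- layout@n_plot_rows * layout@n_plot_cols
  if (is(canopy, "CanopySpec")) canopy <- rep(list(canopy), nplots)
  if (length(canopy) != nplots)
    stop("canopy list length must equal n_plot_rows * n_plot_cols")
  ok <- vapply(canopy, function(s) is(s, "CanopySpec"), logical(1))
  if (!all(ok)) stop("canopy must be CanopySpec objects")
  set.seed(as.integer(seed))

  ext <- fieldExtent(layout)
  area <- (ext["x1"] - ext["x0"]) * (ext["y1"] - ext["y0"])
  n_ground <- max(4L, round(ground_density * area))
  gx <- runif(n_ground, ext["x0"], ext["x1"])
  gy <- runif(n_ground, ext["y0"], ext["y1"])
  gz <- terrainZ(terrain, gx, gy)
  if (terrain@ground_roughness_sd > 0)
    gz <- gz + rnorm(n_ground, 0, terrain@ground_roughness_sd / 100)

  xs <- list(gx); ys <- list(gy); zs <- list(gz)
  cls <- list(rep(LAS_GROUND, n_ground))
  truth <- vector("list", nplots)
  k <- 0L
  for (r in seq_len(layout@n_plot_rows)) {
    for (cc in seq_len(layout@n_plot_cols)) {
      k <- k + 1L
      spec <- canopy[[k]]
      rect <- plotRect(layout, r, cc)
      n_c <- round(spec@point_density * layout@plot_length *
                     layout@plot_width * spec@coverage_fraction)
      if (n_c > 0) {
        # row-concentrated returns plus inter-row canopy closure: by the
        # heading stage the canopy fills the footprint, but the drill rows
        # still dominate the return density (stripe periodicity)
        onRow <- runif(n_c) < row_fraction
        rows <- sample.int(layout@drill_rows_per_plot, n_c, replace = TRUE)
        yc <- (rect["y0"] + rect["y1"]) / 2
        row_y <- yc + (rows - (layout@drill_rows_per_plot + 1) / 2) *
          layout@drill_row_spacing
        py <- ifelse(onRow, row_y + rnorm(n_c, 0, row_scatter_sd),
                     runif(n_c, rect["y0"], rect["y1"]))
        py <- pmin(pmax(py, rect["y0"]), rect["y1"])
        px <- runif(n_c, rect["x0"],
                    rect["x0"] + layout@plot_length * spec@coverage_fraction)
        h_cm <- spec@mean_height +
          (if (spec@height_sd > 0) rnorm(n_c, 0, spec@height_sd) else 0)
        h_cm <- pmax(h_cm, 0)
        pz <- terrainZ(terrain, px, py) + h_cm / 100
        xs <- c(xs, list(px)); ys <- c(ys, list(py)); zs <- c(zs, list(pz))
        cls <- c(cls, list(rep(LAS_VEGETATION, n_c)))
        m <- max(1L, ceiling(0.10 * n_c))
        h10 <- mean(sort(h_cm, decreasing = TRUE)[seq_len(m)])
        cov <- gridOccupancy(px, py, rect, cell = 0.02)
      } else {
        h_cm <- numeric(0); h10 <- NA_real_; cov <- 0
      }
      truth[[k]] <- data.frame(
        plot_row = r, plot_col = cc, x0 = rect[["x0"]], y0 = rect[["y0"]],
        x1 = rect[["x1"]], y1 = rect[["y1"]],
        true_mean_height_cm = if (n_c > 0) mean(h_cm) else NA_real_,
        true_h10_cm = h10, true_coverage = cov, n_canopy_points = n_c)
    }
  }
  cloud <- PointCloud3D(unlist(xs), unlist(ys), unlist(zs),
                        unlist(cls), zUnit = "m")
  list(cloud = cloud, truth = do.call(rbind, truth))
}

# fraction of occupied cells over a rectangular footprint
gridOccupancy <- function(x, y, rect, cell = 0.02) {
  nx <- max(1L, ceiling((rect[["x1"]] - rect[["x0"]]) / cell))
  ny <- max(1L, ceiling((rect[["y1"]] - rect[["y0"]]) / cell))
  ix <- pmin(nx - 1, pmax(0, floor((x - rect[["x0"]]) / cell)))
  iy <- pmin(ny - 1, pmax(0, floor((y - rect[["y0"]]) / cell)))
  length(unique(ix * ny + iy)) / (nx * ny)
}

#' Inject sparse high-altitude outlier points
#'
#' Adds \code{n} points above the cloud, each at least \code{min_offset}
#' meters from every original point (guaranteed by placing them at least
#' that far above the highest original return). Original points are
#' untouched; injected points are left unclassified so the denoiser is
#' not told the answer.
#'
#' @param cloud a [PointCloud3D-class].
#' @param n number of outliers (>= 0).
#' @param min_offset minimum distance to every original point, meters (> 0).
#' @param seed integer seed for reproducible placement.
#' @return A new [PointCloud3D-class] with the outliers appended.
#' @export
injectOutliers <- function(cloud, n, min_offset = 2, seed = 1) {
  if (n < 0) stop("n must be >= 0")
  if (min_offset <= 0) stop("min_offset must be > 0")
  if (n == 0) return(cloud)
  set.seed(as.integer(seed))
  zmax <- max(cloud@z)
  ox <- runif(n, min(cloud@x), max(cloud@x))
  oy <- runif(n, min(cloud@y), max(cloud@y))
  oz <- zmax + min_offset + runif(n, 0, 2 * min_offset)
  new("PointCloud3D",
      x = c(cloud@x, ox), y = c(cloud@y, oy), z = c(cloud@z, oz),
      classification = c(cloud@classification, rep(LAS_UNCLASSIFIED, n)),
      zUnit = cloud@zUnit)
}
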