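# Shared fixtures built in code.

# small flat-terrain field, deterministic
smallField <- function(rows = 1, cols = 1, mean_height = 80, height_sd = 0,
                       density = 300, slope_x = 0, roughness = 0, seed = 1,
                       ground_density = 150, coverage = 1, ...) {
  generateField(
    fieldLayout(n_plot_rows = rows, n_plot_cols = cols),
    canopySpec(mean_height = mean_height, height_sd = height_sd,
               coverage_fraction = coverage, point_density = density),
    terrainSpec(slope_x = slope_x, ground_roughness_sd = roughness,
                base_elevation = 10),
    seed = seed, ground_density = ground_density, ...)
}

# brute-force mean distance to the k nearest neighbours (O(n^2) oracle)
bruteKnnMeanDist <- function(x, y, z, k) {
  D <- as.matrix(dist(cbind(x, y, z)))
  vapply(seq_along(x), function(i) mean(sort(D[i, -i])[seq_len(k)]),
         numeric(1))
}

# brute-force outlier set under the avg + k_sd * sd rule
bruteOutlierSet <- function(x, y, z, n_neighbors, k_sd) {
  d <- bruteKnnMeanDist(x, y, z, n_neighbors)
  which(d > mean(d) + k_sd * sd(d))
}

# truth plot rectangles in 1-based inclusive pixel coordinates of a CHM
truthRectsPx <- function(truth, origin, resolution = 1) {
  tp <- geoToPixel(cbind(truth$x0, truth$y1), origin, resolution)
  bp <- geoToPixel(cbind(truth$x1, truth$y0), origin, resolution)
  data.frame(row_id = truth$plot_row, col_id = truth$plot_col,
             tx0 = tp[, 1] + 1, ty0 = tp[, 2] + 1, tx1 = bp[, 1],
             ty1 = bp[, 2])
}

# run denoise -> ground -> normalize -> CHM -> segmentation on a block
segmentBlock <- function(fld, k = 3, layout = NULL) {
  dn <- denoiseCloud(fld$cloud, k = k)
  nm <- normalizeHeights(classifyGround(dn$clean))
  chm <- rasterizeChm(nm)
  img <- encodeGrayscale(chm)
  grid <- segmentPlots(img, layout = layout, origin = chm@origin)
  list(grid = grid, chm = chm, img = img, cloud = nm)
}

# max absolute boundary error (pixels) of a segmented grid vs truth
boundaryError <- function(grid, truth, chm) {
  p <- plotRecords(grid)
  tr <- truthRectsPx(truth, chm@origin, chmResolution(chm))
  m <- merge(p, tr, by = c("row_id", "col_id"))
  stopifnot(nrow(m) == nrow(truth))
  max(abs(cbind(m$x0 - m$tx0, m$y0 - m$ty0, m$x1 - m$tx1, m$y1 - m$ty1)))
}
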