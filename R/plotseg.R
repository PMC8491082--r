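# Plot segmentation: threshold -> directional Sobel edges -> restricted
# Hough line fit -> line merging -> lattice of plot rectangles ->
# entropy-weighted sampling-window refinement.

# box mean via summed-area table, edge-normalized (window clipped at
# borders); half = half-width, window = 2*half + 1
boxMean <- function(m, half) {
  nr <- nrow(m); nc <- ncol(m)
  S <- matrix(0, nr + 1, nc + 1)
  S[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  r0 <- pmax(0L, seq_len(nr) - half - 1L); r1 <- pmin(nr, seq_len(nr) + half)
  c0 <- pmax(0L, seq_len(nc) - half - 1L); c1 <- pmin(nc, seq_len(nc) + half)
  sums <- S[r1 + 1L, c1 + 1L, drop = FALSE] - S[r0 + 1L, c1 + 1L, drop = FALSE] -
    S[r1 + 1L, c0 + 1L, drop = FALSE] + S[r0 + 1L, c0 + 1L, drop = FALSE]
  cnt <- outer(r1 - r0, c1 - c0)
  sums / cnt
}

#' Binarize a CHM image into an initial canopy mask
#'
#' Pixelwise OR of a global (Otsu) threshold and a local adaptive (moving
#' box mean + offset) threshold, so canopy is recovered even on a
#' non-uniform background.
#'
#' @param img 8-bit CHM image (integer matrix 0-255).
#' @param window local-threshold window size, pixels (odd).
#' @param offset local-threshold offset, gray levels.
#' @return logical matrix, canopy pixels TRUE.
#' @export
binarizeCanopy <- function(img, window = 51, offset = 5) {
  img <- unclass(img)
  attr(img, "valid") <- NULL
  rng <- range(img)
  if (rng[1] == rng[2]) {
    warning("constant image: empty canopy mask")
    return(matrix(FALSE, nrow = nrow(img), ncol = ncol(img)))
  }
  tglob <- EBImage::otsu(EBImage::Image(img / 255), range = c(0, 1)) * 255
  maskg <- img > tglob
  maskl <- img > boxMean(img, half = window %/% 2) + offset
  maskg | maskl
}

# Sobel gradients (3x3), replicate boundary
sobelGradients <- function(m) {
  shift <- function(dr, dc) {
    nr <- nrow(m); nc <- ncol(m)
    ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    m[ri, ci, drop = FALSE]
  }
  gx <- (shift(-1, 1) + 2 * shift(0, 1) + shift(1, 1)) -
        (shift(-1, -1) + 2 * shift(0, -1) + shift(1, -1))
  gy <- (shift(1, -1) + 2 * shift(1, 0) + shift(1, 1)) -
        (shift(-1, -1) + 2 * shift(-1, 0) + shift(-1, 1))
  list(gx = gx, gy = gy)
}

#' Detect near-axis plot boundary lines in a canopy mask
#'
#' Sobel edges of the requested direction are accumulated by a Hough-style
#' vote over intercepts, with the angle search restricted to within 2
#' degrees of the axis (the CHM is aligned beforehand). Peaks with at
#' least \code{min_line_votes} of the perpendicular image dimension in
#' votes are kept after non-maximum suppression.
#'
#' @param mask logical canopy mask from [binarizeCanopy].
#' @param orientation `"horizontal"` (constant-row lines) or
#'   `"vertical"`.
#' @param min_line_votes minimum votes as a fraction of the line length.
#' @param angles candidate angles about the axis, degrees (within +/- 2;
#'   the default single angle relies on the CHM having been aligned, with
#'   residual tilt absorbed by the vote pooling).
#' @param nms_radius suppression radius, pixels.
#' @return data.frame: intercept (pixels, at the image center line;
#'   refined to the vote centroid around each peak), votes, angle.
#' @export
detectPlotLines <- function(mask, orientation = c("horizontal", "vertical"),
                            min_line_votes = 0.4, angles = 0,
                            nms_radius = 10) {
  orientation <- match.arg(orientation)
  if (!any(mask)) stop("empty canopy mask")
  g <- sobelGradients(mask * 1)
  # strict dominance: a 45-degree edge votes for neither orientation
  if (orientation == "horizontal") {
    sel <- abs(g$gy) > 0.5 & abs(g$gy) > abs(g$gx)
    pos <- which(sel, arr.ind = TRUE)
    along <- pos[, 2]; across <- pos[, 1]
    L <- ncol(mask); nBins <- nrow(mask)
  } else {
    sel <- abs(g$gx) > 0.5 & abs(g$gx) > abs(g$gy)
    pos <- which(sel, arr.ind = TRUE)
    along <- pos[, 1]; across <- pos[, 2]
    L <- nrow(mask); nBins <- ncol(mask)
  }
  if (!length(along)) return(emptyLines())
  centre <- (L + 1) / 2
  best <- rep(0, nBins); bestAng <- rep(NA_real_, nBins)
  raw0 <- NULL
  for (a in angles) {
    b <- round(across - tan(a * pi / 180) * (along - centre))
    b <- b[b >= 1 & b <= nBins]
    v <- tabulate(b, nbins = nBins)
    if (a == angles[which.min(abs(angles))]) raw0 <- v
    # a TIN-derived mask boundary is ragged at the point-spacing scale, so
    # votes for one physical edge spread over a few intercepts: pool them
    v <- as.numeric(stats::filter(v, rep(1, 5), sides = 2))
    v[is.na(v)] <- 0
    better <- v > best
    best[better] <- v[better]
    bestAng[better] <- a
  }
  # absolute floor plus a relative cut against the strongest edge, so
  # off-angle shadows of real edges do not pass
  thr <- max(min_line_votes * L, 0.5 * max(best))
  cand <- which(best >= thr)
  if (!length(cand)) return(emptyLines())
  o <- cand[order(-best[cand], cand)]
  keep <- integer(0)
  for (b in o)
    if (!length(keep) || all(abs(keep - b) > nms_radius)) keep <- c(keep, b)
  keep <- sort(keep)
  # sub-bin refinement: vote centroid in a small window around each peak
  refined <- vapply(keep, function(b) {
    w <- max(1, b - 3):min(nBins, b + 3)
    if (sum(raw0[w]) > 0) sum(w * raw0[w]) / sum(raw0[w]) else as.numeric(b)
  }, numeric(1))
  data.frame(intercept = refined, votes = best[keep], angle = bestAng[keep])
}

emptyLines <- function() {
  data.frame(intercept = numeric(0), votes = numeric(0), angle = numeric(0))
}

#' Merge nearby detected lines
#'
#' Lines of one orientation whose intercepts chain within
#' \code{merge_distance} pixels collapse to a single line at their
#' vote-weighted mean intercept, so one line represents each gap. The
#' merged band extent (lo, hi) is retained: for an inter-plot gap the two
#' flanking edge lines delimit the gap, and the lattice builder uses the
#' band edges as plot boundaries.
#'
#' @param lines data.frame from [detectPlotLines].
#' @param merge_distance maximum intercept difference to merge, pixels.
#' @return data.frame: intercept, votes, lo, hi, sorted by intercept.
#' @export
mergeLines <- function(lines, merge_distance = 30) {
  if (merge_distance <= 0) stop("merge_distance must be > 0")
  if (!nrow(lines))
    return(data.frame(intercept = numeric(0), votes = numeric(0),
                      lo = numeric(0), hi = numeric(0)))
  o <- order(lines$intercept)
  x <- lines$intercept[o]; v <- lines$votes[o]
  grp <- cumsum(c(1, diff(x) > merge_distance))
  data.frame(
    intercept = as.numeric(tapply(x * v, grp, sum) / tapply(v, grp, sum)),
    votes = as.numeric(tapply(v, grp, sum)),
    lo = as.numeric(tapply(x, grp, min)),
    hi = as.numeric(tapply(x, grp, max)))
}

#' Assemble plot rectangles from merged boundary lines
#'
#' Plot rectangles are the cells of the lattice spanned by the merged
#' horizontal and vertical gap bands (cell edges at the inner band
#' limits). When a [FieldLayout-class] is supplied and the detected count
#' disagrees with it, evenly spaced baselines over the mask extent
#' replace the deficient orientation. Row/column ids count from the
#' top-left.
#'
#' @param hlines,vlines merged lines from [mergeLines] (horizontal =
#'   constant-row).
#' @param layout optional [FieldLayout-class] prior.
#' @param mask optional canopy mask (needed for layout baselines).
#' @param resolution,origin raster metadata carried into the grid.
#' @return A [PlotGrid-class] (refined rectangles initialized to the
#'   bounding rectangles).
#' @export
buildPlotMasks <- function(hlines, vlines, layout = NULL, mask = NULL,
                           resolution = 1, origin = c(0, 0)) {
  if (!is.null(layout)) {
    if (nrow(hlines) != layout@n_plot_rows + 1)
      hlines <- baselineBands(layout@n_plot_rows, mask, "horizontal")
    if (nrow(vlines) != layout@n_plot_cols + 1)
      vlines <- baselineBands(layout@n_plot_cols, mask, "vertical")
  }
  if (nrow(hlines) < 2 || nrow(vlines) < 2)
    stop("need at least 2 boundary lines per orientation (or a layout)")
  nr <- nrow(hlines) - 1; nc <- nrow(vlines) - 1
  recs <- vector("list", nr * nc)
  k <- 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      k <- k + 1
      # a band edge centroid sits on the canopy/gap transition, half a
      # pixel outside the outermost plot pixel
      y0 <- round(hlines$hi[i] + 0.5); y1 <- round(hlines$lo[i + 1] - 0.5)
      x0 <- round(vlines$hi[j] + 0.5); x1 <- round(vlines$lo[j + 1] - 0.5)
      if (y1 <= y0 || x1 <= x0)
        stop("degenerate plot cell between merged lines; check ",
             "merge_distance / line detection")
      recs[[k]] <- data.frame(row_id = i, col_id = j, x0 = x0, y0 = y0,
                              x1 = x1, y1 = y1)
    }
  }
  p <- do.call(rbind, recs)
  p$rx0 <- p$x0; p$ry0 <- p$y0; p$rx1 <- p$x1; p$ry1 <- p$y1
  p$refined_flag <- "none"
  new("PlotGrid", plots = p, resolution = resolution, origin = origin)
}

baselineBands <- function(n, mask, orientation) {
  if (is.null(mask))
    stop("a canopy mask is required to derive layout baselines")
  idx <- if (orientation == "horizontal") which(rowSums(mask) > 0)
         else which(colSums(mask) > 0)
  if (!length(idx)) stop("empty canopy mask")
  b <- seq(min(idx) - 1, max(idx) + 1, length.out = n + 1)
  data.frame(intercept = b, votes = rep(1, n + 1), lo = b, hi = b)
}

# local entropy of gray values (histogram over nbins) in a square window
localEntropy <- function(img, half = 4, nbins = 16) {
  img <- unclass(img); attr(img, "valid") <- NULL
  bins <- pmin(floor(img / (256 / nbins)), nbins - 1L)
  ent <- matrix(0, nrow(img), ncol(img))
  for (b in 0:(nbins - 1L)) {
    p <- boxMean((bins == b) * 1, half)
    nz <- p > 0
    ent[nz] <- ent[nz] - p[nz] * log2(p[nz])
  }
  ent
}

#' Refine a plot's sampling window by its entropy-weighted centroid
#'
#' Computes the local grayscale entropy inside the plot rectangle, shrinks
#' the rectangle by \code{margin} per side and recenters it at the
#' entropy-weighted centroid (clipped to the plot bounds), so the
#' sampling area avoids plot edges and texture-free failure regions.
#' Texture-free (zero-entropy) plots fall back to the geometric center.
#'
#' @param img 8-bit CHM image.
#' @param rect c(x0, y0, x1, y1) plot rectangle, 1-based inclusive pixels.
#' @param entropy_window entropy neighbourhood size, pixels (odd).
#' @param margin shrink fraction per side (default 0.1).
#' @param nbins histogram bins for the entropy estimate.
#' @return list: \code{rect} (refined c(x0, y0, x1, y1)) and \code{flag}
#'   (`"entropy"` or `"fallback_center"`).
#' @export
refinePlotWindow <- function(img, rect, entropy_window = 9, margin = 0.1,
                             nbins = 16) {
  img <- unclass(img); attr(img, "valid") <- NULL
  x0 <- rect[1]; y0 <- rect[2]; x1 <- rect[3]; y1 <- rect[4]
  if (x0 < 1 || y0 < 1 || x1 > ncol(img) || y1 > nrow(img))
    stop("plot rectangle outside the image")
  sub <- img[y0:y1, x0:x1, drop = FALSE]
  ent <- localEntropy(sub, half = entropy_window %/% 2, nbins = nbins)
  tot <- sum(ent)
  w <- (x1 - x0 + 1) * (1 - 2 * margin)
  h <- (y1 - y0 + 1) * (1 - 2 * margin)
  if (tot <= 1e-9) {
    cx <- (x0 + x1) / 2; cy <- (y0 + y1) / 2
    flag <- "fallback_center"
  } else {
    cx <- x0 - 1 + sum(ent * col(ent)) / tot
    cy <- y0 - 1 + sum(ent * row(ent)) / tot
    flag <- "entropy"
  }
  rx0 <- round(cx - w / 2); rx1 <- round(cx + w / 2)
  ry0 <- round(cy - h / 2); ry1 <- round(cy + h / 2)
  if (rx0 < x0) { rx1 <- rx1 + (x0 - rx0); rx0 <- x0 }
  if (rx1 > x1) { rx0 <- rx0 - (rx1 - x1); rx1 <- x1 }
  if (ry0 < y0) { ry1 <- ry1 + (y0 - ry0); ry0 <- y0 }
  if (ry1 > y1) { ry0 <- ry0 - (ry1 - y1); ry1 <- y1 }
  list(rect = c(x0 = max(x0, rx0), y0 = max(y0, ry0),
                x1 = min(x1, rx1), y1 = min(y1, ry1)), flag = flag)
}

#' Segment an encoded CHM image into a plot grid
#'
#' Convenience wrapper running [binarizeCanopy], [detectPlotLines] in both
#' orientations, [mergeLines], [buildPlotMasks] and per-plot
#' [refinePlotWindow].
#'
#' @param img 8-bit CHM image from [encodeGrayscale].
#' @param layout optional [FieldLayout-class] prior.
#' @param resolution cm per pixel (used for the default merge distance and
#'   grid metadata).
#' @param merge_distance gap-merging distance, pixels; defaults to the
#'   layout gap width (30 cm) over the resolution.
#' @param min_line_votes,entropy_window,margin passed through.
#' @param origin geo origin of the image.
#' @return A [PlotGrid-class].
#' @export
segmentPlots <- function(img, layout = NULL, resolution = 1,
                         merge_distance = 35 / resolution,
                         min_line_votes = 0.4, entropy_window = 9,
                         margin = 0.1, origin = c(0, 0)) {
  mask <- binarizeCanopy(img)
  hl <- mergeLines(detectPlotLines(mask, "horizontal",
                                   min_line_votes = min_line_votes),
                   merge_distance)
  vl <- mergeLines(detectPlotLines(mask, "vertical",
                                   min_line_votes = min_line_votes),
                   merge_distance)
  grid <- buildPlotMasks(hl, vl, layout = layout, mask = mask,
                         resolution = resolution, origin = origin)
  p <- grid@plots
  for (i in seq_len(nrow(p))) {
    r <- refinePlotWindow(img, c(p$x0[i], p$y0[i], p$x1[i], p$y1[i]),
                          entropy_window = entropy_window, margin = margin)
    p$rx0[i] <- r$rect[["x0"]]; p$ry0[i] <- r$rect[["y0"]]
    p$rx1[i] <- r$rect[["x1"]]; p$ry1[i] <- r$rect[["y1"]]
    p$refined_flag[i] <- r$flag
  }
  grid@plots <- p
  grid
}
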