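# synthetic CHM-like images built directly (plots at a set intensity on a
# darker background), plus full generator-truth cases

syntheticGridImage <- function(nrows = 3, ncols = 3, plot_h = 150,
                               plot_w = 250, gap = 30, border = 30,
                               fg = 120, bg = 5, gradient = 0) {
  H <- 2 * border + nrows * plot_h + (nrows - 1) * gap
  W <- 2 * border + ncols * plot_w + (ncols - 1) * gap
  im <- matrix(bg, H, W)
  rects <- list()
  for (i in seq_len(nrows)) for (j in seq_len(ncols)) {
    r0 <- border + (i - 1) * (plot_h + gap) + 1
    c0 <- border + (j - 1) * (plot_w + gap) + 1
    im[r0:(r0 + plot_h - 1), c0:(c0 + plot_w - 1)] <- fg
    rects[[length(rects) + 1]] <- c(x0 = c0, y0 = r0, x1 = c0 + plot_w - 1,
                                    y1 = r0 + plot_h - 1)
  }
  if (gradient != 0)
    im <- im + matrix(rep(seq(0, gradient, length.out = W), each = H), H, W)
  im <- pmin(pmax(round(im), 0), 255)
  storage.mode(im) <- "integer"
  list(img = im, rects = do.call(rbind, rects))
}

test_that("binarization recovers plots on uniform and gradient backgrounds", {
  g <- syntheticGridImage()
  mask <- binarizeCanopy(g$img)
  plotPx <- g$img == 120
  expect_gte(mean(mask[plotPx]), 0.99)
  expect_lte(mean(mask[!plotPx]), 0.01)

  gg <- syntheticGridImage(gradient = 60, bg = 5)
  maskg <- binarizeCanopy(gg$img)
  fgPx <- gg$img >= 120
  expect_gte(mean(maskg[fgPx]), 0.95)

  expect_warning(empty <- binarizeCanopy(matrix(7L, 50, 50)), "constant")
  expect_false(any(empty))
})

test_that("line detection finds the gap edges of a 3x3 grid", {
  g <- syntheticGridImage()
  mask <- binarizeCanopy(g$img)
  for (orient in c("horizontal", "vertical")) {
    lines <- detectPlotLines(mask, orient)
    merged <- mergeLines(lines, 35)
    expect_equal(nrow(merged), 4)  # 2 outer edges + 2 inner gaps
    # merged inner-gap intercepts sit at the gap centers
    tr <- if (orient == "horizontal") g$rects[, c("y0", "y1")]
          else g$rects[, c("x0", "x1")]
    gaps <- sort(unique(tr[, 2]))[1:2] + 15.5
    expect_lte(max(abs(sort(merged$intercept)[2:3] - gaps)), 2)
  }
})

test_that("a single solid rectangle yields two lines per orientation", {
  im <- matrix(0L, 200, 300)
  im[51:150, 101:200] <- 120L
  mask <- binarizeCanopy(im)
  expect_equal(nrow(detectPlotLines(mask, "horizontal")), 2)
  expect_equal(nrow(detectPlotLines(mask, "vertical")), 2)
})

test_that("diagonal stripes produce no axis-aligned lines", {
  im <- matrix(0L, 300, 300)
  idx <- which((row(im) + col(im)) %% 60 < 25)
  im[idx] <- 120L
  mask <- binarizeCanopy(im)
  expect_equal(nrow(detectPlotLines(mask, "horizontal")), 0)
  expect_equal(nrow(detectPlotLines(mask, "vertical")), 0)
})

test_that("line merging pools close intercepts by vote weight", {
  lines <- data.frame(intercept = c(100, 102), votes = c(300, 100),
                      angle = 0)
  m <- mergeLines(lines, 5)
  expect_equal(nrow(m), 1)
  expect_equal(m$intercept, (100 * 300 + 102 * 100) / 400)
  expect_equal(m$lo, 100); expect_equal(m$hi, 102)

  far <- data.frame(intercept = c(100, 200), votes = c(1, 1), angle = 0)
  expect_equal(mergeLines(far, 5)$intercept, c(100, 200))
  expect_equal(nrow(mergeLines(emptyLines <- data.frame(
    intercept = numeric(0), votes = numeric(0)), 5)), 0)
})

test_that("plot masks assemble into the lattice with top-left ids", {
  g <- syntheticGridImage()
  grid <- segmentPlots(g$img)
  expect_equal(length(grid), 9)
  p <- plotRecords(grid)
  expect_equal(sort(unique(p$row_id)), 1:3)
  expect_equal(sort(unique(p$col_id)), 1:3)
  tr <- g$rects
  colnames(tr) <- c("tx0", "ty0", "tx1", "ty1")
  m <- merge(p, data.frame(row_id = rep(1:3, each = 3),
                           col_id = rep(1:3, 3), tr))
  expect_equal(nrow(m), 9)
  err <- abs(cbind(m$x0 - m$tx0, m$y0 - m$ty0, m$x1 - m$tx1,
                   m$y1 - m$ty1))
  expect_lte(max(err), 3)
  # refined windows nest inside the bounding rectangles
  expect_true(all(p$rx0 >= p$x0 & p$rx1 <= p$x1 &
                  p$ry0 >= p$y0 & p$ry1 <= p$y1))
})

test_that("segmentation is invariant to a +20 global intensity offset", {
  g <- syntheticGridImage(fg = 120, bg = 5)
  im2 <- pmin(g$img + 20L, 255L)
  p1 <- plotRecords(segmentPlots(g$img))
  p2 <- plotRecords(segmentPlots(im2))
  expect_identical(p1[, c("x0", "y0", "x1", "y1")],
                   p2[, c("x0", "y0", "x1", "y1")])
})

test_that("a degraded mask with a layout prior still yields the full grid", {
  g <- syntheticGridImage()
  im <- g$img
  # fill 40% of the gap pixels (lodging): corrupt random gap pixels
  set.seed(33)
  gapPx <- which(im == 5)
  im[sample(gapPx, round(0.4 * length(gapPx)))] <- 120L
  layout <- fieldLayout(n_plot_rows = 3, n_plot_cols = 3)
  grid <- segmentPlots(im, layout = layout)
  expect_equal(length(grid), 9)
  # with a layout the count always equals rows x cols
  expect_equal(length(unique(plotRecords(grid)$row_id)), 3)
})

test_that("entropy refinement recenters on textured regions", {
  set.seed(34)
  # uniform texture: centroid stays at the geometric center
  im <- matrix(sample(0:255, 120 * 160, replace = TRUE), 120, 160)
  r <- refinePlotWindow(im, c(11, 11, 150, 110))
  expect_equal(r$flag, "entropy")
  ctr <- c((r$rect[["x0"]] + r$rect[["x1"]]) / 2,
           (r$rect[["y0"]] + r$rect[["y1"]]) / 2)
  expect_lte(abs(ctr[1] - (11 + 150) / 2), 2)
  expect_lte(abs(ctr[2] - (11 + 110) / 2), 2)

  # texture only in the left half: centroid shifts left and matches the
  # brute-force entropy-map centroid
  im2 <- matrix(100L, 120, 160)
  im2[, 1:80] <- matrix(sample(0:255, 120 * 80, replace = TRUE), 120, 80)
  r2 <- refinePlotWindow(im2, c(11, 11, 150, 110), entropy_window = 9,
                         margin = 0.3)
  sub <- im2[11:110, 11:150]
  ent <- matrix(0, nrow(sub), ncol(sub))
  for (rr in seq_len(nrow(sub))) for (cc in seq_len(ncol(sub))) {
    w <- sub[max(1, rr - 4):min(nrow(sub), rr + 4),
             max(1, cc - 4):min(ncol(sub), cc + 4)]
    p <- table(pmin(floor(w / 16), 15)) / length(w)
    ent[rr, cc] <- -sum(p * log2(p))
  }
  cx_bf <- 10 + sum(ent * col(ent)) / sum(ent)
  cy_bf <- 10 + sum(ent * row(ent)) / sum(ent)
  expect_lte(abs((r2$rect[["x0"]] + r2$rect[["x1"]]) / 2 - cx_bf), 1.5)
  expect_lte(abs((r2$rect[["y0"]] + r2$rect[["y1"]]) / 2 - cy_bf), 1.5)
  expect_lt((r2$rect[["x0"]] + r2$rect[["x1"]]) / 2, (11 + 150) / 2)

  # all-flat plot: geometric-center fallback with flag
  r3 <- refinePlotWindow(matrix(0L, 100, 100), c(11, 11, 90, 90))
  expect_equal(r3$flag, "fallback_center")
})

test_that("segmentation boundaries hold across random seeds on clean gaps", {
  for (s in 1:4) {
    fld <- smallField(rows = 2, cols = 2, height_sd = 3, density = 800,
                      ground_density = 200, roughness = 0.5, seed = 200 + s)
    seg <- segmentBlock(fld)
    expect_equal(length(seg$grid), 4)
    expect_lte(boundaryError(seg$grid, fld$truth, seg$chm), 3)
  }
})
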