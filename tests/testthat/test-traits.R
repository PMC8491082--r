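test_that("plot height averages the top decile with the ceiling rule", {
  expect_equal(plotHeight(rep(50, 100)), 50)
  expect_equal(plotHeight(1:100), mean(91:100))   # 95.5
  expect_equal(plotHeight(1:100, 0.25), mean(76:100))
  expect_equal(plotHeight(c(5, 3), 0.10), 5)      # ceil(0.2) = 1
  expect_error(plotHeight(numeric(0)), "empty")
})

test_that("plot height equals an independent brute-force top-decile mean", {
  set.seed(40)
  for (n in c(17, 1000, 4999)) {
    z <- round(rnorm(n, 80, 6), 3)  # rounding makes ties likely
    m <- ceiling(0.1 * n)
    oracle <- mean(z[order(z, decreasing = TRUE)][1:m])
    expect_equal(plotHeight(z), oracle)
  }
  fld <- smallField(mean_height = 80, height_sd = 3, density = 600,
                    seed = 41)
  nm <- normalizeHeights(classifyGround(fld$cloud))
  ag <- nm@z[nm@classification == 5]
  expect_lte(abs(plotHeight(ag) - fld$truth$true_h10_cm), 2)
})

test_that("canopy coverage saturates, halves, and zeroes as constructed", {
  fld <- smallField(density = 2000, height_sd = 2, seed = 42)
  cl <- fld$cloud
  sel <- cl@classification == 5
  rect <- with(fld$truth, c(x0, y0, x1, y1))
  z_cm <- (cl@z[sel] - 10) * 100
  cov <- canopyCoverage(cl@x[sel], cl@y[sel], z_cm, rect)
  expect_gte(as.numeric(cov), 0.98)

  half <- smallField(density = 2000, height_sd = 2, coverage = 0.5,
                     seed = 43)
  ch <- half$cloud
  selh <- ch@classification == 5
  covh <- canopyCoverage(ch@x[selh], ch@y[selh], (ch@z[selh] - 10) * 100,
                         rect)
  expect_lte(abs(as.numeric(covh) - 0.5), 0.05)

  none <- canopyCoverage(numeric(0), numeric(0), numeric(0), rect)
  expect_equal(as.numeric(none), 0)
  expect_equal(attr(none, "flag"), "empty")
})

test_that("alpha-shape surface area matches analytic references", {
  # cube corners, alpha much larger than the cube: convex hull area 6
  cx <- rep(c(0, 1), each = 4); cy <- rep(rep(c(0, 1), each = 2), 2)
  cz <- rep(c(0, 1), 4)
  a <- surfaceArea3d(cx, cy, cz * 100, voxel_size = 5, alpha = 1000)
  expect_equal(a, 6, tolerance = 1e-4)

  # flat dense plane of footprint A: thin slab, area in [A, 2A + eps]
  set.seed(44)
  n <- 4000
  px <- runif(n, 0, 2); py <- runif(n, 0, 1.5)
  A <- 2 * 1.5
  a2 <- surfaceArea3d(px, py, rep(80, n))
  expect_gte(a2, A)
  expect_lte(a2, 2 * A + 0.8)   # eps: ragged slab rim

  # too few voxels flagged
  tf <- surfaceArea3d(c(0, 1), c(0, 1), c(0, 100))
  expect_true(is.na(tf))
  expect_equal(attr(tf, "flag"), "too_few_voxels")
})

test_that("rough canopies have strictly larger surface area than smooth", {
  areas <- vapply(c(0, 6), function(sd) {
    fld <- smallField(mean_height = 80, height_sd = sd, density = 600,
                      seed = 45)
    cl <- fld$cloud; sel <- cl@classification == 5
    surfaceArea3d(cl@x[sel], cl@y[sel], (cl@z[sel] - 10) * 100)
  }, numeric(1))
  expect_gt(areas[2], areas[1])
})

test_that("surface area is monotone in height texture across seeds", {
  sds <- c(1, 3, 5, 7)
  rho <- vapply(1:10, function(s) {
    areas <- vapply(sds, function(sd) {
      fld <- smallField(mean_height = 80, height_sd = sd, density = 400,
                        seed = 500 + s)
      cl <- fld$cloud; sel <- cl@classification == 5
      surfaceArea3d(cl@x[sel], cl@y[sel], (cl@z[sel] - 10) * 100)
    }, numeric(1))
    cor(sds, areas, method = "spearman")
  }, numeric(1))
  expect_gt(mean(rho), 0.9)
})

test_that("voxel indices count occupancy, not point density", {
  vx <- voxelIndices(0.01, 0.01, 1,
                     bounds = list(x = c(0, 0.5), y = c(0, 0.5),
                                   z = c(0, 0.005)))
  expect_equal(vx$vi_3d, 1 / (10 * 10 * 1))

  set.seed(46)
  n <- 500
  px <- runif(n); py <- runif(n); pz <- runif(n, 0, 30)
  v1 <- voxelIndices(px, py, pz)
  v2 <- voxelIndices(rep(px, 2), rep(py, 2), rep(pz, 2))
  expect_equal(v1$vi_3d, v2$vi_3d)
  expect_equal(v1$pi_3d, v2$pi_3d)

  # everything occupied -> vi = 1
  g <- expand.grid(x = seq(0.025, 0.475, by = 0.05),
                   y = seq(0.025, 0.475, by = 0.05))
  vall <- voxelIndices(g$x, g$y, rep(2.5, nrow(g)),
                       bounds = list(x = c(0, 0.5), y = c(0, 0.5),
                                     z = c(0, 0.05)))
  expect_equal(vall$vi_3d, 1)
  expect_error(voxelIndices(numeric(0), numeric(0), numeric(0)), "empty")
})

test_that("the trait table has one flagged-complete row per plot", {
  fld <- smallField(rows = 1, cols = 2, height_sd = 3, density = 500,
                    ground_density = 200, seed = 47)
  seg <- segmentBlock(fld)
  traits <- computeTraits(seg$cloud, seg$grid)
  expect_equal(nrow(traits), 2)
  expect_true(all(!is.na(traits$height_h10)))
  expect_true(all(traits$coverage >= 0 & traits$coverage <= 1))
  expect_true(all(traits$surface_index <= 1, na.rm = TRUE))
  expect_equal(max(traits$surface_index, na.rm = TRUE), 1)
  # NaN/NA only alongside a flag
  bad <- !complete.cases(traits[, c("height_h10", "surface_area_raw")])
  expect_true(all(traits$flag[bad] != "ok"))
})
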