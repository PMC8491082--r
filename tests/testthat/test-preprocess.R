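test_that("denoiser equals the O(n^2) brute-force oracle on a grid", {
  g <- expand.grid(x = 1:10, y = 1:10, z = 1)
  d <- denoiseCloud(PointCloud3D(g$x, g$y, g$z), n_neighbors = 8, k = 1)
  oracle <- bruteOutlierSet(g$x, g$y, g$z, 8, 1)
  expect_equal(length(d$outliers), length(oracle))
  expect_setequal(d$outliers@x, g$x[oracle])

  # a far-away point must be flagged
  g2 <- rbind(g, c(1000, 1000, 1000))
  d2 <- denoiseCloud(PointCloud3D(g2$x, g2$y, g2$z), n_neighbors = 8, k = 1)
  expect_true(1000 %in% d2$outliers@x)
  oracle2 <- bruteOutlierSet(g2$x, g2$y, g2$z, 8, 1)
  expect_setequal(paste(d2$outliers@x, d2$outliers@y),
                  paste(g2$x[oracle2], g2$y[oracle2]))
})

test_that("denoiser matches the oracle exactly on random clouds", {
  for (s in 1:6) {
    set.seed(s)
    n <- sample(300:800, 1)
    cl <- PointCloud3D(runif(n, 0, 10), runif(n, 0, 10), runif(n, 0, 2))
    cl <- injectOutliers(cl, sample(0:5, 1), 3, seed = s)
    d <- denoiseCloud(cl, n_neighbors = 20, k = 1)
    oracle <- bruteOutlierSet(cl@x, cl@y, cl@z, 20, 1)
    expect_setequal(paste(d$outliers@x, d$outliers@y),
                    paste(cl@x[oracle], cl@y[oracle]))
  }
})

test_that("re-applying the denoiser flags no more than the first pass", {
  set.seed(20)
  cl <- PointCloud3D(runif(500), runif(500), runif(500))
  d1 <- denoiseCloud(cl, n_neighbors = 15, k = 1.5)
  d2 <- denoiseCloud(d1$clean, n_neighbors = 15, k = 1.5)
  expect_lte(length(d2$outliers), length(d1$outliers))
  expect_error(denoiseCloud(PointCloud3D(1:5, 1:5, 1:5), n_neighbors = 10),
               "more than")
})

test_that("ground classification recovers generator labels", {
  bare <- generateField(fieldLayout(n_plot_rows = 1, n_plot_cols = 1),
                        canopySpec(point_density = 1e-6),
                        terrainSpec(ground_roughness_sd = 1), seed = 5,
                        ground_density = 300)
  cl <- classifyGround(bare$cloud)
  expect_gte(mean(cl@classification == 2), 0.99)

  fld <- smallField(mean_height = 80, height_sd = 2, roughness = 1,
                    density = 400, ground_density = 300, seed = 6)
  cl2 <- classifyGround(fld$cloud)
  truth <- fld$cloud@classification
  expect_gte(mean(cl2@classification[truth == 2] == 2), 0.99)
  expect_gte(mean(cl2@classification[truth == 5] == 5), 0.99)

  single <- classifyGround(PointCloud3D(0, 0, 5))
  expect_identical(single@classification, 2L)
  expect_error(classifyGround(PointCloud3D(numeric(0), numeric(0),
                                           numeric(0))), "empty")
})

test_that("terrain normalization flattens slopes and zeroes ground", {
  # 2-degree slope, no canopy: residuals within 1 cm
  bare <- generateField(fieldLayout(n_plot_rows = 1, n_plot_cols = 2),
                        canopySpec(point_density = 1e-6),
                        terrainSpec(slope_x = 0.035,
                                    ground_roughness_sd = 0.3),
                        seed = 7, ground_density = 400)
  cl <- classifyGround(bare$cloud)
  nm <- normalizeHeights(cl)
  expect_lte(max(abs(nm@z)), 1)
  expect_true(all(nm@z[nm@classification == 2] == 0))

  # slope + uniform canopy: above-ground heights recovered
  fld <- smallField(mean_height = 80, height_sd = 0, slope_x = 0.035,
                    roughness = 0.3, density = 400, ground_density = 300,
                    seed = 8)
  nm2 <- normalizeHeights(classifyGround(fld$cloud))
  ag <- nm2@z[nm2@classification == 5]
  expect_true(all(abs(ag - 80) <= 2))

  # flat ground at 5 m: ground exactly zero
  flat <- PointCloud3D(runif(200), runif(200), rep(5, 200),
                       rep(2L, 200))
  nm3 <- normalizeHeights(flat)
  expect_true(all(nm3@z == 0))
  expect_error(normalizeHeights(PointCloud3D(1, 1, 1, 5L)), "ground")
})

test_that("normalization is idempotent", {
  fld <- smallField(height_sd = 3, roughness = 0.5, seed = 9)
  nm1 <- normalizeHeights(classifyGround(fld$cloud))
  nm2 <- normalizeHeights(nm1)
  expect_lte(max(abs(nm1@z - nm2@z)), 1e-6)
})

test_that("TIN interpolation reproduces planes and constants exactly", {
  r <- tinInterpolate(c(0, 1, 0), c(0, 0, 1), c(1, 3, 4), resolution = 10)
  v <- r$values
  ctrx <- r$origin[1] + (col(v) - 0.5) * 0.1
  ctry <- r$origin[2] - (row(v) - 0.5) * 0.1
  plane <- 2 * ctrx + 3 * ctry + 1
  expect_lte(max(abs(v - plane), na.rm = TRUE), 1e-6)

  set.seed(21)
  r2 <- tinInterpolate(runif(50), runif(50), rep(50, 50), resolution = 10)
  expect_true(all(abs(r2$values - 50) < 1e-9, na.rm = TRUE))
  expect_error(tinInterpolate(1:5, 2 * (1:5), rnorm(5)), "collinear")
})

test_that("TIN raster equals brute-force barycentric interpolation", {
  set.seed(22)
  n <- 200
  x <- runif(n); y <- runif(n); z <- sin(4 * x) + y^2
  tri <- delaunayTriangles(x, y)
  r <- tinInterpolate(x, y, z, resolution = 10)
  v <- r$values
  res_m <- 0.1
  oracle <- matrix(NA_real_, nrow(v), ncol(v))
  for (rr in seq_len(nrow(v))) {
    py <- r$origin[2] - (rr - 0.5) * res_m
    for (cc in seq_len(ncol(v))) {
      px <- r$origin[1] + (cc - 0.5) * res_m
      for (t in seq_len(nrow(tri))) {
        i <- tri[t, 1]; j <- tri[t, 2]; k <- tri[t, 3]
        det <- (x[j] - x[i]) * (y[k] - y[i]) - (y[j] - y[i]) * (x[k] - x[i])
        w1 <- ((x[j] - px) * (y[k] - py) - (y[j] - py) * (x[k] - px)) / det
        w2 <- ((x[k] - px) * (y[i] - py) - (y[k] - py) * (x[i] - px)) / det
        w3 <- 1 - w1 - w2
        if (w1 >= -1e-9 && w2 >= -1e-9 && w3 >= -1e-9) {
          oracle[rr, cc] <- w1 * z[i] + w2 * z[j] + w3 * z[k]
          break
        }
      }
    }
  }
  same <- is.na(v) == is.na(oracle)
  expect_gte(mean(same), 0.999)  # hull-edge cells may differ by fp ties
  ok <- !is.na(v) & !is.na(oracle)
  expect_lte(max(abs(v[ok] - oracle[ok])), 1e-9)
})

test_that("Delaunay triangulation satisfies the empty-circumcircle property", {
  set.seed(23)
  x <- runif(150); y <- runif(150)
  tri <- delaunayTriangles(x, y)
  # Euler: triangles = 2n - 2 - hull_size for a triangulated point set
  hull <- grDevices::chull(x, y)
  expect_equal(nrow(tri), 2 * 150 - 2 - length(hull))
  for (t in seq_len(nrow(tri))) {
    v <- tri[t, ]
    ax <- x[v[1]]; ay <- y[v[1]]; bx <- x[v[2]]; by <- y[v[2]]
    cx <- x[v[3]]; cy <- y[v[3]]
    D <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / D
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / D
    r2 <- (ax - ux)^2 + (ay - uy)^2
    d2 <- (x - ux)^2 + (y - uy)^2
    inside <- d2 < r2 * (1 - 1e-9)
    inside[v] <- FALSE
    expect_false(any(inside))
  }
})

test_that("classification plus normalization recovers canopy heights", {
  errs <- vapply(1:10, function(s) {
    fld <- smallField(mean_height = 75, height_sd = 2, roughness = 1,
                      density = 400, ground_density = 300, seed = 100 + s)
    nm <- normalizeHeights(classifyGround(fld$cloud))
    ag <- nm@z[nm@classification == 5]
    h10 <- plotHeight(ag, 0.10)
    h10 - fld$truth$true_h10_cm
  }, numeric(1))
  expect_lte(sqrt(mean(errs^2)), 2)
})
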