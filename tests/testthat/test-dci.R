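test_that("the spectrum of a constant image is a single DC peak", {
  spec <- dftMagnitude(matrix(37L, 41, 41))
  s <- spec@scaled
  ctr <- spec@center
  expect_equal(which(s == max(s)), (ctr[2] - 1) * nrow(s) + ctr[1])
  off <- s[-((ctr[2] - 1) * nrow(s) + ctr[1])]
  expect_true(all(off < max(s)))
  expect_lte(diff(range(off)), 1e-9)
})

test_that("a vertical grating peaks at the closed-form frequency", {
  N <- 64; p <- 8
  im <- matrix(rep(128 + 100 * cos(2 * pi * (0:(N - 1)) / p), each = N),
               N, N)
  spec <- dftMagnitude(im)
  ctr <- spec@center
  rowline <- spec@logmag[ctr[1], ]
  peaks <- order(rowline, decreasing = TRUE)[1:3]
  expect_setequal(peaks, c(ctr[2], ctr[2] - N / p, ctr[2] + N / p))
})

test_that("centered magnitude is conjugate-symmetric and obeys Parseval", {
  set.seed(50)
  im <- matrix(runif(61 * 45, 0, 255), 61, 45)
  spec <- dftMagnitude(im)
  lm <- spec@logmag
  rot <- lm[rev(seq_len(nrow(lm))), rev(seq_len(ncol(lm)))]
  expect_lte(max(abs(lm - rot)), 1e-6)
  FT <- fft(im)
  expect_equal(sum(Mod(FT)^2) / length(im), sum(im^2),
               tolerance = 1e-6)
})

test_that("diagonal sampling spans a..b with palindromic symmetry", {
  set.seed(51)
  im <- matrix(runif(301 * 301, 0, 255), 301, 301)
  spec <- dftMagnitude(im)
  sm <- sampleDiagonal(spec, -100, 100)
  expect_length(sm$amplitudes, 201)
  expect_equal(sm$frequencies, -100:100)
  expect_equal(sm$amplitudes, rev(sm$amplitudes), tolerance = 1e-6)
  # constant image: center sample is the unique diagonal maximum
  smc <- sampleDiagonal(dftMagnitude(matrix(9L, 301, 301)), -100, 100)
  expect_equal(which.max(smc$amplitudes), 101)
  expect_error(sampleDiagonal(spec, 5, 5), "a must be")
  # small image: profile resampled onto the full span
  small <- sampleDiagonal(dftMagnitude(im[1:41, 1:41]), -100, 100)
  expect_length(small$amplitudes, 201)
})

test_that("Gaussian fitting recovers known parameters", {
  x <- -100:100
  y <- 180 * exp(-(x - 0)^2 / (2 * 25^2))
  fit <- fitGaussianCurve(x, y)
  expect_true(fit@fitOk)
  expect_equal(fit@A, 180, tolerance = 1e-6)
  expect_equal(fit@mu, 0, tolerance = 1e-6)
  expect_equal(fit@sigma, 25, tolerance = 1e-6)

  set.seed(52)
  yn <- y + rnorm(length(y), 0, 0.05 * 180)
  fitn <- fitGaussianCurve(x, yn)
  expect_true(fitn@fitOk)
  expect_lte(abs(fitn@A - 180) / 180, 0.05)
  expect_lte(abs(fitn@sigma - 25) / 25, 0.05)

  flat <- fitGaussianCurve(x, rep(3, 201))
  expect_false(flat@fitOk)
  expect_equal(flat@fitted, flat@raw)
})

test_that("trapezoidal AUC is exact for constants/linears and matches erf", {
  expect_equal(curveAuc(seq(-100, 100, by = 1), y = rep(3, 201)), 600)
  xs <- c(0, 0.12, 0.3, 0.77, 1)
  expect_equal(curveAuc(xs, y = xs), 0.5)
  x <- -100:100
  gauss <- exp(-x^2 / (2 * 20^2))
  analytic <- 20 * sqrt(2 * pi) *
    (stats::pnorm(100 / 20) - stats::pnorm(-100 / 20))
  expect_lte(abs(curveAuc(x, y = gauss) - analytic) / analytic, 1e-3)
  expect_error(curveAuc(1, y = 1), "2 samples")
})

test_that("AUC of a fitted curve matches fine-grid numeric integration", {
  x <- -100:100
  y <- 140 * exp(-(x - 5)^2 / (2 * 30^2))
  curve <- fitGaussianCurve(x, y)
  auc <- curveAuc(curve)
  fine <- seq(-100, 100, length.out = 20001)
  ref <- sum(curve@A * exp(-(fine - curve@mu)^2 / (2 * curve@sigma^2))) *
    diff(fine)[1]
  expect_lte(abs(auc - ref) / ref, 1e-3)
})

test_that("curvature matches circle, line, and Gaussian-apex references", {
  t <- seq(0, 2 * pi, length.out = 2001)
  r <- 3.7
  k <- curvatureProfile(r * cos(t), r * sin(t))
  expect_lte(max(abs(k[!is.na(k)] - 1 / r)), 1e-6)

  lin <- curvatureProfile(1:100, 2 * (1:100) + 5)
  expect_lte(max(abs(lin[!is.na(lin)])), 1e-9)

  x <- -100:100
  A <- 180; sig <- 25
  curve <- fitGaussianCurve(x, A * exp(-x^2 / (2 * sig^2)))
  expect_lte(abs(curveCurvature(curve) - A / sig^2) / (A / sig^2), 1e-3)
  expect_error(curvatureProfile(1:3, 1:3), "5 samples")
})

test_that("3DCI normalization matches the hand-computed example", {
  out <- compute3dci(c(10, 20))
  expect_equal(round(out, 4), c(0.2040, 0.7053))
  expect_true(all(out > 0 & out < 1))
})

test_that("3DCI stays in (0,1) and is scale invariant", {
  set.seed(53)
  for (i in 1:20) {
    v <- runif(sample(2:30, 1), 0.1, 50)
    if (min(v) == max(v)) next
    y <- compute3dci(v)
    expect_true(all(y > 0 & y < 1))
    expect_equal(compute3dci(v * 17.3), y, tolerance = 1e-12)
  }
  expect_error(compute3dci(c(5, 5)), "zero range")
  expect_error(compute3dci(c(-1, 2)), "positive")
  expect_error(compute3dci(3), "cohort")
})

test_that("3DCI increases with canopy height texture end to end", {
  sds <- c(2, 4, 6, 8)
  aucs <- vapply(sds, function(sd) {
    fld <- smallField(mean_height = 80, height_sd = sd, density = 800,
                      ground_density = 200, seed = 60)
    nm <- normalizeHeights(classifyGround(fld$cloud))
    chm <- rasterizeChm(nm)
    img <- encodeGrayscale(chm)
    tr <- truthRectsPx(fld$truth, chm@origin)
    sub <- unclass(img)[ceiling(tr$ty0 + 3):floor(tr$ty1 - 3),
                        ceiling(tr$tx0 + 3):floor(tr$tx1 - 3)]
    sm <- sampleDiagonal(dftMagnitude(sub))
    curveAuc(fitGaussianCurve(sm$frequencies, sm$amplitudes))
  }, numeric(1))
  dci <- compute3dci(aucs)
  expect_true(all(diff(dci) > 0))
})

test_that("denser spike texture flattens the curve apex", {
  # lower variance + denser sampling = denser canopy -> smaller curvature
  curv <- vapply(c(2, 8), function(sd) {
    fld <- smallField(mean_height = 80, height_sd = sd, density = 800,
                      ground_density = 200, seed = 61)
    nm <- normalizeHeights(classifyGround(fld$cloud))
    img <- encodeGrayscale(rasterizeChm(nm))
    tr <- truthRectsPx(fld$truth, chmOrigin(rasterizeChm(nm)))
    sub <- unclass(img)[ceiling(tr$ty0 + 3):floor(tr$ty1 - 3),
                        ceiling(tr$tx0 + 3):floor(tr$tx1 - 3)]
    sm <- sampleDiagonal(dftMagnitude(sub))
    curveCurvature(fitGaussianCurve(sm$frequencies, sm$amplitudes))
  }, numeric(1))
  expect_lt(curv[1], curv[2])
})
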