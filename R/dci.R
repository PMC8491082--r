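# Spectral canopy-structure analysis: plot CHM -> centered 2D DFT
# log-magnitude -> diagonal frequency sampling -> Gaussian-fitted canopy
# structural curve -> AUC, apex curvature, and cohort-normalized 3DCI.

#' SpectralImage: centered DFT log-magnitude of a plot CHM
#'
#' @slot logmag centered log(1 + |F|) magnitude (pre-rescale).
#' @slot scaled the same grid on a 0-255 scale, calibrated against the
#'   theoretical DC maximum of an image of this size (so values are
#'   comparable across plots rather than stretched per image).
#' @slot center (row, col) of the DC component after centering.
#' @export
setClass("SpectralImage",
  representation(logmag = "matrix", scaled = "matrix", center = "integer"),
  validity = function(object) {
    if (!all(dim(object@logmag) == dim(object@scaled)))
      return("logmag and scaled must agree in size")
    TRUE
  })

setMethod("show", "SpectralImage", function(object) {
  d <- dim(object@logmag)
  cat(sprintf("SpectralImage %d x %d, DC at (%d, %d)\n", d[1], d[2],
              object@center[1], object@center[2]))
})

fftshiftOrder <- function(n) {
  s <- ceiling(n / 2)
  c((s + 1):n, 1:s)
}

#' Centered log-magnitude spectrum of a plot CHM image
#'
#' Forward 2D DFT of the grayscale plot image; the magnitude is
#' log-compressed (log(1 + |F|)), the DC component shifted to the center
#' cell, and the grid linearly rescaled to 0-255 for sampling. For real
#' input the centered magnitude is symmetric under 180-degree rotation.
#'
#' @param img numeric/integer matrix (8-bit plot CHM).
#' @return A [SpectralImage-class].
#' @export
dftMagnitude <- function(img) {
  img <- unclass(img); attr(img, "valid") <- NULL
  if (length(img) == 0) stop("empty image")
  FT <- stats::fft(img)
  lm <- log1p(Mod(FT))
  lm <- lm[fftshiftOrder(nrow(lm)), fftshiftOrder(ncol(lm)), drop = FALSE]
  # fixed calibration against the theoretical DC bound (all pixels white),
  # not the per-image min-max: amplitudes stay comparable across plots and
  # monotone in the underlying spectral energy
  scaled <- 255 * lm / log1p(255 * length(img))
  new("SpectralImage", logmag = lm, scaled = scaled,
      center = as.integer(c(floor(nrow(lm) / 2) + 1, floor(ncol(lm) / 2) + 1)))
}

#' Sample the spectrogram diagonal
#'
#' Reads the 0-255 grayscale values along the main diagonal through the
#' centered DC, at integer diagonal steps \code{a..b}. When the image
#' cannot host the requested span the available diagonal profile is
#' linearly resampled onto the \code{b - a + 1} points so the frequency
#' domain stays fixed across plot sizes. Optionally the two diagonals
#' are averaged.
#'
#' @param spec a [SpectralImage-class].
#' @param a,b frequency span (defaults -100, 100).
#' @param both average the main and anti-diagonal profiles.
#' @return list: \code{frequencies} (a..b), \code{amplitudes}.
#' @export
sampleDiagonal <- function(spec, a = -100, b = 100, both = FALSE) {
  if (a >= b) stop("a must be < b")
  ctr <- spec@center
  d <- dim(spec@scaled)
  smax <- min(ctr[1] - 1, d[1] - ctr[1], ctr[2] - 1, d[2] - ctr[2])
  readDiag <- function(sign_c) {
    s <- (-smax):smax
    spec@scaled[cbind(ctr[1] + s, ctr[2] + sign_c * s)]
  }
  prof <- readDiag(1)
  if (both) prof <- (prof + rev(readDiag(-1))) / 2
  freqs <- a:b
  need <- max(abs(a), abs(b))
  if (smax >= need) {
    amps <- prof[smax + 1 + freqs]
  } else {
    if (smax < 2) stop("image too small to sample a diagonal profile")
    amps <- stats::approx(seq(-smax, smax), prof,
                          xout = seq(-smax, smax, length.out = b - a + 1))$y
  }
  list(frequencies = freqs, amplitudes = amps)
}

#' Fit a Gaussian canopy structural curve
#'
#' Least-squares fit of \code{A * exp(-(x - mu)^2 / (2 sigma^2))} through
#' the sampled frequency/amplitude pairs (Levenberg-Marquardt). On fit
#' failure or constant amplitudes the curve is flagged and the raw
#' samples retained as the fitted values.
#'
#' @param frequencies,amplitudes samples from [sampleDiagonal].
#' @return A [CanopyCurve-class] (fit only; AUC/curvature not yet set).
#' @export
fitGaussianCurve <- function(frequencies, amplitudes) {
  x <- as.numeric(frequencies); yv <- as.numeric(amplitudes)
  if (length(x) < 5) stop("need at least 5 samples")
  if (stats::sd(yv) == 0) {
    return(new("CanopyCurve", x = x, raw = yv, fitted = yv, fitOk = FALSE))
  }
  mu0 <- x[which.max(yv)]
  A0 <- max(yv)
  w <- pmax(yv - min(yv), 0)
  s0 <- sqrt(sum(w * (x - mu0)^2) / max(sum(w), 1e-9))
  if (!is.finite(s0) || s0 < 1) s0 <- max(1, diff(range(x)) / 10)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = list(A = A0, mu = as.numeric(mu0), sigma = s0),
      fn = function(p) yv - p$A * exp(-(x - p$mu)^2 / (2 * p$sigma^2)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) {
    return(new("CanopyCurve", x = x, raw = yv, fitted = yv, fitOk = FALSE))
  }
  cf <- unlist(fit$par)
  sigma <- abs(cf[["sigma"]])
  fitted <- cf[["A"]] * exp(-(x - cf[["mu"]])^2 / (2 * sigma^2))
  new("CanopyCurve", x = x, raw = yv, fitted = fitted, A = cf[["A"]],
      mu = cf[["mu"]], sigma = sigma, fitOk = TRUE)
}

#' Trapezoidal area under a canopy structural curve
#'
#' \code{sum_k (f(x_{k+1}) + f(x_k)) / 2 * dx_k} over the sampled span;
#' exact for constant and linear integrands. Computed on the fitted curve
#' by default (the raw samples are an option).
#'
#' @param curve a [CanopyCurve-class], or a numeric vector of x with
#'   \code{y} supplied.
#' @param y amplitudes when \code{curve} is a plain x vector.
#' @param use_fitted integrate the Gaussian-fitted values (default) or
#'   the raw samples.
#' @return the area.
#' @export
curveAuc <- function(curve, y = NULL, use_fitted = TRUE) {
  if (is(curve, "CanopyCurve")) {
    x <- curve@x
    y <- if (use_fitted) curve@fitted else curve@raw
  } else x <- curve
  if (length(x) < 2) stop("need at least 2 samples")
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

#' Curvature profile of a sampled parametric curve
#'
#' \code{|x'y'' - x''y'| / (x'^2 + y'^2)^(3/2)} with derivatives taken by
#' central differences over the sample index.
#'
#' @param x,y parametric samples.
#' @return curvature at each interior sample (ends NA).
#' @export
curvatureProfile <- function(x, y) {
  n <- length(x)
  if (n < 5) stop("need at least 5 samples")
  d1 <- function(v) c(NA, (v[-(1:2)] - v[1:(n - 2)]) / 2, NA)
  d2 <- function(v) c(NA, v[-(1:2)] + v[1:(n - 2)] - 2 * v[2:(n - 1)], NA)
  xp <- d1(x); yp <- d1(y); xpp <- d2(x); ypp <- d2(y)
  abs(xp * ypp - xpp * yp) / (xp^2 + yp^2)^1.5
}

#' Apex curvature of a canopy structural curve
#'
#' Curvature of the fitted curve evaluated at the sample nearest the
#' Gaussian center (the curve apex); a denser, more uniform canopy gives
#' a flatter, lower-curvature apex.
#'
#' @param curve a [CanopyCurve-class].
#' @return curvature at the apex.
#' @export
curveCurvature <- function(curve) {
  stopifnot(is(curve, "CanopyCurve"))
  k <- curvatureProfile(curve@x, curve@fitted)
  apex <- if (curve@fitOk && is.finite(curve@mu))
    which.min(abs(curve@x - curve@mu)) else which.max(curve@fitted)
  apex <- min(max(apex, 2L), length(k) - 1L)
  k[apex]
}

#' Normalize curve areas into the 3D canopy index
#'
#' Min-max normalization against widened theoretical bounds: MinValue is
#' 59.3% of the cohort minimum and MaxValue 129.4% of the cohort maximum,
#' so every normalized value lies strictly inside (0, 1) and the index is
#' invariant to positive rescaling of the cohort.
#'
#' @param auc positive AUC values for a cohort of plots (length >= 2,
#'   min < max).
#' @return normalized 3DCI values in (0, 1).
#' @export
compute3dci <- function(auc) {
  if (length(auc) < 2) stop("need a cohort of at least 2 values")
  if (any(!is.finite(auc) | auc <= 0))
    stop("AUC values must be positive and finite")
  lo <- min(auc); hi <- max(auc)
  if (lo == hi) stop("zero range: identical AUC values")
  minv <- 0.593 * lo
  maxv <- 1.294 * hi
  (auc - minv) / (maxv - minv)
}

#' Canopy structural curves and 3DCI for all plots of a run
#'
#' Extracts each plot's refined-window CHM sub-image, computes the
#' centered DFT log-magnitude, samples the diagonal, fits the Gaussian
#' curve, and derives AUC and apex curvature; AUCs are cohort-normalized
#' into the 3DCI.
#'
#' @param img 8-bit CHM image from [encodeGrayscale].
#' @param grid a [PlotGrid-class].
#' @param a,b frequency span (defaults -100, 100).
#' @param both average both diagonals.
#' @param use_refined sample the refined rectangles (default).
#' @return data.frame: row_id, col_id, auc, curvature, dci_3d, fit
#'   parameters and fit_ok flag.
#' @export
dciForPlots <- function(img, grid, a = -100, b = 100, both = FALSE,
                        use_refined = TRUE) {
  p <- grid@plots
  rows <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    px <- if (use_refined) c(p$rx0[i], p$ry0[i], p$rx1[i], p$ry1[i])
          else c(p$x0[i], p$y0[i], p$x1[i], p$y1[i])
    sub <- unclass(img)[px[2]:px[4], px[1]:px[3], drop = FALSE]
    spec <- dftMagnitude(sub)
    sm <- sampleDiagonal(spec, a, b, both = both)
    curve <- fitGaussianCurve(sm$frequencies, sm$amplitudes)
    rows[[i]] <- data.frame(
      row_id = p$row_id[i], col_id = p$col_id[i],
      auc = curveAuc(curve), curvature = curveCurvature(curve),
      A = curve@A, mu = curve@mu, sigma = curve@sigma,
      fit_ok = curve@fitOk)
  }
  out <- do.call(rbind, rows)
  out$dci_3d <- NA_real_
  ok <- is.finite(out$auc) & out$auc > 0
  if (sum(ok) >= 2 && min(out$auc[ok]) < max(out$auc[ok]))
    out$dci_3d[ok] <- compute3dci(out$auc[ok])
  out
}
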