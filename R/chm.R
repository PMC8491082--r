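#' Rasterize the canopy height model
#'
#' Builds the digital surface model from the above-ground points of a
#' normalized cloud: points are decimated to the highest return per cell
#' and TIN-interpolated at cell centers. Triangles longer than
#' \code{max_edge} meters are not interpolated across, so bare inter-plot
#' gaps stay no-data instead of being bridged with canopy heights.
#'
#' @param cloud a normalized [PointCloud3D-class] (ground at 0, zUnit cm).
#' @param resolution cm per pixel (default 1).
#' @param max_edge TIN bridging cap, meters (default 0.2; 0 disables).
#' @param bbox optional geo extent c(x0, y0, x1, y1).
#' @return A [CHMRaster-class].
#' @export
rasterizeChm <- function(cloud, resolution = 1, max_edge = 0.2,
                         bbox = NULL) {
  if (cloud@zUnit != "cm")
    stop("cloud must be normalized first (zUnit cm)", call. = FALSE)
  ag <- aboveGroundPoints(cloud)
  if (length(ag) == 0) {
    warning("no above-ground points: returning an all-no-data CHM")
    h <- matrix(NA_real_, 1, 1)
    org <- if (length(cloud)) c(min(cloud@x), max(cloud@y)) else c(0, 0)
    return(new("CHMRaster", heights = h, resolution = resolution,
               origin = org))
  }
  if (is.null(bbox)) bbox <- c(min(cloud@x), min(cloud@y),
                               max(cloud@x), max(cloud@y))
  res_m <- resolution / 100
  # highest return per cell
  ix <- floor((ag@x - bbox[1]) / res_m)
  iy <- floor((ag@y - bbox[2]) / res_m)
  id <- paste(ix, iy)
  o <- order(ag@z, decreasing = TRUE)
  keep <- o[!duplicated(id[o])]
  z <- pmax(ag@z[keep], 0)
  r <- tinInterpolate(ag@x[keep], ag@y[keep], z, resolution = resolution,
                      max_edge = max_edge, bbox = bbox)
  vals <- r$values
  vals[!is.na(vals) & vals < 0] <- 0
  new("CHMRaster", heights = vals, resolution = resolution,
      origin = r$origin)
}

#' Encode a CHM as an 8-bit grayscale image
#'
#' Linear height-to-intensity calibration: \code{h_black} cm maps to 0 and
#' \code{h_white} cm to 255 (round-half-up), clamped to \[0, 255\] so
#' canopies taller than the white point saturate rather than error.
#' No-data cells encode as 0; the validity mask is carried in the
#' \code{"valid"} attribute.
#'
#' @param chm a [CHMRaster-class] (or plain height matrix in cm).
#' @param h_black,h_white calibration endpoints, cm (default 0 and 160).
#' @return integer matrix of intensities 0-255 with a logical
#'   \code{"valid"} attribute.
#' @export
encodeGrayscale <- function(chm, h_black = 0, h_white = 160) {
  if (h_white <= h_black) stop("h_white must exceed h_black")
  h <- if (is(chm, "CHMRaster")) chm@heights else chm
  valid <- !is.na(h)
  g <- floor(255 * (h - h_black) / (h_white - h_black) + 0.5)
  g <- pmin(pmax(g, 0), 255)
  g[!valid] <- 0
  storage.mode(g) <- "integer"
  attr(g, "valid") <- valid
  g
}

#' Invert the grayscale encoding back to heights
#' @param img integer matrix from [encodeGrayscale].
#' @inheritParams encodeGrayscale
#' @export
decodeGrayscale <- function(img, h_black = 0, h_white = 160) {
  h_black + (h_white - h_black) * (img / 255)
}

# homography mapping (X, Y) destination -> (x, y) source, from 4 pairs
perspectiveMatrix <- function(src, dst) {
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    X <- dst[i, 1]; Y <- dst[i, 2]; x <- src[i, 1]; y <- src[i, 2]
    A[2 * i - 1, ] <- c(X, Y, 1, 0, 0, 0, -X * x, -Y * x)
    A[2 * i, ]     <- c(0, 0, 0, X, Y, 1, -X * y, -Y * y)
    b[2 * i - 1] <- x
    b[2 * i] <- y
  }
  p <- solve(A, b)
  matrix(c(p, 1), 3, 3, byrow = TRUE)
}

#' Align a CHM image with a four-marker perspective transform
#'
#' Warps the quadrilateral spanned by the four markers (pixel positions,
#' order upper-left, upper-right, lower-left, lower-right) onto an
#' axis-aligned rectangle whose width and height are the means of the
#' opposing marker-edge lengths, using bilinear resampling. Markers
#' already forming an axis-aligned rectangle reduce to a plain crop.
#'
#' @param image numeric/integer matrix (row 1 = top).
#' @param markers 4 x 2 matrix of (col, row) pixel positions in the
#'   canonical order.
#' @return warped matrix.
#' @export
alignPerspective <- function(image, markers) {
  m <- as.matrix(markers)
  if (nrow(m) != 4 || ncol(m) != 2) stop("markers must be 4 x 2 (col, row)")
  # ring order UL, UR, LR, LL must be simple (consistent turn direction)
  ring <- m[c(1, 2, 4, 3), ]
  cross <- sapply(1:4, function(i) {
    a <- ring[i, ]; b <- ring[i %% 4 + 1, ]; c <- ring[(i + 1) %% 4 + 1, ]
    (b[1] - a[1]) * (c[2] - b[2]) - (b[2] - a[2]) * (c[1] - b[1])
  })
  if (any(cross > 0) && any(cross < 0))
    stop("markers are self-intersecting; expected UL, UR, LL, LR order")
  edge <- function(i, j) sqrt(sum((m[i, ] - m[j, ])^2))
  W <- max(1L, round(mean(c(edge(1, 2), edge(3, 4)))))
  H <- max(1L, round(mean(c(edge(1, 3), edge(2, 4)))))
  dst <- cbind(c(0, W, 0, W), c(0, 0, H, H))
  Hm <- perspectiveMatrix(m, dst)
  out_c <- rep(seq_len(W) - 0.5, each = H)
  out_r <- rep(seq_len(H) - 0.5, times = W)
  den <- Hm[3, 1] * out_c + Hm[3, 2] * out_r + Hm[3, 3]
  sx <- (Hm[1, 1] * out_c + Hm[1, 2] * out_r + Hm[1, 3]) / den
  sy <- (Hm[2, 1] * out_c + Hm[2, 2] * out_r + Hm[2, 3]) / den
  vals <- bilinearImage(image, sx, sy)
  matrix(vals, nrow = H, ncol = W)
}

# bilinear sample of an image (pixel (r, c) centered at (c - 0.5, r - 0.5)
# in (x, y) = (col, row) coordinates); outside -> 0
bilinearImage <- function(im, x, y) {
  nr <- nrow(im); nc <- ncol(im)
  fx <- x - 0.5; fy <- y - 0.5
  # snap near-integer positions to avoid resampling fuzz on exact crops
  fx <- ifelse(abs(fx - round(fx)) < 1e-9, round(fx), fx)
  fy <- ifelse(abs(fy - round(fy)) < 1e-9, round(fy), fy)
  c0 <- floor(fx); r0 <- floor(fy)
  wx <- fx - c0; wy <- fy - r0
  gv <- function(r, cc) {
    ok <- r >= 0 & r <= nr - 1 & cc >= 0 & cc <= nc - 1
    v <- numeric(length(r))
    v[ok] <- im[cbind(r[ok] + 1, cc[ok] + 1)]
    v
  }
  (1 - wy) * ((1 - wx) * gv(r0, c0) + wx * gv(r0, c0 + 1)) +
    wy * ((1 - wx) * gv(r0 + 1, c0) + wx * gv(r0 + 1, c0 + 1))
}
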