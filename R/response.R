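# Nitrogen-response analytics: classify varieties into four response
# classes from their canopy structural index across treatment levels, and
# rank varieties in a banded, weighted performance matrix.

#' Classify a variety's nitrogen response
#'
#' With d = (low, medium, high) mean canopy structural index and a
#' similarity tolerance tau:
#' \itemize{
#'   \item Class 1: all pairwise differences exceed tau and the index
#'     decreases from low to high N (strong, graded response).
#'   \item Class 2: low and medium are similar, high drops below medium
#'     by more than tau (responds only above medium N).
#'   \item Class 3: medium and high are similar, medium sits below low by
#'     more than tau (response saturates at medium N).
#'   \item Class 4: medium is the minimum and high rises above it by more
#'     than tau (best response at medium N).
#' }
#'
#' @param d_low,d_med,d_high mean 3DCI at the three treatment levels (or
#'   \code{d_low} a length-3 vector).
#' @param tau similarity tolerance (default 0.02).
#' @return integer class 1-4, or NA (unclassified) with a
#'   \code{"diagnostics"} attribute.
#' @export
classifyNResponse <- function(d_low, d_med = NULL, d_high = NULL,
                              tau = 0.02) {
  if (is.null(d_med) && length(d_low) == 3) {
    d_high <- d_low[3]; d_med <- d_low[2]; d_low <- d_low[1]
  }
  if (anyNA(c(d_low, d_med, d_high)))
    stop("all three treatment levels are required")
  d <- c(low = d_low, med = d_med, high = d_high)
  pw <- c(abs(d[1] - d[2]), abs(d[2] - d[3]), abs(d[1] - d[3]))
  cls <- NA_integer_
  if (all(pw > tau) && d[1] > d[2] && d[2] > d[3]) {
    cls <- 1L
  } else if (abs(d[1] - d[2]) <= tau && d[3] < d[2] - tau) {
    cls <- 2L
  } else if (abs(d[2] - d[3]) <= tau && d[2] < d[1] - tau) {
    cls <- 3L
  } else if (d[2] <= d[1] && d[2] <= d[3] && d[3] > d[2] + tau) {
    cls <- 4L
  }
  if (is.na(cls))
    attr(cls, "diagnostics") <- sprintf(
      "no class pattern at tau=%g: d=(%.4f, %.4f, %.4f)", tau, d[1], d[2],
      d[3])
  cls
}

# banded rank from percentage deviation about the trimmed mean;
# bands lower-inclusive / upper-exclusive, outermost unbounded
deviationRank <- function(dev) {
  ifelse(dev >= 15, 5L,
  ifelse(dev >= 7.5, 4L,
  ifelse(dev >= -7.5, 3L,
  ifelse(dev >= -15, 2L, 1L))))
}

# height is penalized symmetrically: both very short and very tall rank low
heightRank <- function(dev) {
  ad <- abs(dev)
  ifelse(ad <= 7.5, 3L, ifelse(ad <= 15, 2L, 1L))
}

#' Build the banded, weighted performance matrix
#'
#' Each trait value is expressed as a percentage deviation from the
#' trait's trimmed mean and banded into ranks 1-5 (above +15% rank 5,
#' +7.5 to +15% rank 4, -7.5 to +7.5% rank 3, -15 to -7.5% rank 2, below
#' -15% rank 1). Height is the exception: both very short and very tall
#' are undesirable, so the band is symmetric (within 7.5% rank 3, 7.5-15%
#' rank 2, beyond 15% rank 1). The weighted score is the weight vector
#' (summing to 1, yield components weighted most) applied to the ranks;
#' varieties are returned sorted by score, best first.
#'
#' @param traits data.frame with a \code{variety} column and the trait
#'   columns named in \code{weights}.
#' @param weights named trait weights summing to 1 (default GN 0.25, SN
#'   0.25, dci_3d 0.2, surface 0.2, height 0.1).
#' @param trim trimmed-mean trim fraction per tail (default 0.1).
#' @param height_trait name of the symmetric-penalty trait.
#' @return list: \code{ranks} (varieties x traits integer matrix),
#'   \code{deviations}, \code{trimmed_means}, \code{scores} (data.frame
#'   sorted by weighted score).
#' @export
performanceMatrix <- function(traits,
                              weights = c(GN = 0.25, SN = 0.25,
                                          dci_3d = 0.2, surface = 0.2,
                                          height = 0.1),
                              trim = 0.1, height_trait = "height") {
  if (!"variety" %in% names(traits)) stop("traits needs a variety column")
  if (nrow(traits) < 3) stop("need at least 3 varieties")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  tn <- names(weights)
  if (!all(tn %in% names(traits)))
    stop("missing trait columns: ",
         paste(setdiff(tn, names(traits)), collapse = ", "))
  vals <- as.matrix(traits[, tn, drop = FALSE])
  if (anyNA(vals)) stop("trait values must be complete")
  tm <- apply(vals, 2, mean, trim = trim)
  if (any(tm == 0)) stop("trimmed mean of zero: deviations undefined")
  dev <- sweep(sweep(vals, 2, tm), 2, tm, "/") * 100
  ranks <- dev
  for (j in seq_along(tn)) {
    ranks[, j] <- if (tn[j] == height_trait) heightRank(dev[, j])
                  else deviationRank(dev[, j])
  }
  storage.mode(ranks) <- "integer"
  rownames(ranks) <- rownames(dev) <- traits$variety
  score <- as.numeric(ranks %*% weights)
  ord <- order(-score, traits$variety)
  list(ranks = ranks, deviations = dev, trimmed_means = tm,
       scores = data.frame(variety = traits$variety,
                           weighted_score = score)[ord, ])
}
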