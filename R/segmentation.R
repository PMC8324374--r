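#' Otsu's optimal gray threshold
#'
#' Selects the gray level \code{t} that maximises the between-class
#' variance \code{w0 * w1 * (mu0 - mu1)^2} of the histogram split into a
#' background class (levels \code{<= t}) and a foreground class (levels
#' \code{> t}). The variance is defined as 0 whenever either class is
#' empty, and ties are broken toward the smallest \code{t}, so the result
#' is deterministic; a single-level histogram yields 0.
#'
#' @param hist integer vector of 256 gray-level counts
#'   (see [grayHistogram()]).
#' @return integer threshold in \[0, 255\].
#' @export
otsuThreshold <- function(hist) {
  if (length(hist) != 256) stop("histogram must have 256 bins")
  if (anyNA(hist) || any(hist < 0)) stop("histogram counts must be >= 0")
  total <- sum(hist)
  if (total == 0) stop("empty histogram")
  levels <- 0:255
  p <- hist / total
  w0 <- cumsum(p)                       # P(level <= t), t = 0..255
  w1 <- 1 - w0
  m <- cumsum(p * levels)
  muT <- m[256]
  sigma <- numeric(256)
  ok <- w0 > 0 & w1 > 0
  sigma[ok] <- (muT * w0[ok] - m[ok])^2 / (w0[ok] * w1[ok])
  which.max(sigma) - 1L                 # first max = smallest t
}

#' Binarize a gray image at a threshold
#'
#' Foreground (1) where the pixel value is strictly greater than
#' \code{t1}; on the B-G difference image the foreground is the
#' nucleus-plus-platelet class.
#'
#' @param gray integer matrix in \[0, 255\].
#' @param t1 gray threshold in \[0, 255\].
#' @return integer 0/1 matrix.
#' @export
binarize <- function(gray, t1) {
  assertGray(gray)
  stopifnot(length(t1) == 1, t1 >= 0, t1 <= 255)
  out <- (gray > t1) * 1L
  storage.mode(out) <- "integer"
  out
}

#' Label connected foreground regions
#'
#' Connected-component labeling of a binary mask with 4- or
#' 8-connectivity. Labels are \code{1..n} in row-major first-encounter
#' order, making the labeling a pure function of the mask.
#'
#' @param mask binary matrix.
#' @param connectivity 4 or 8 (default 8, so that lobes joined by thin
#'   diagonal filaments stay one region).
#' @return a [LabelMap-class].
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  assertMask(mask)
  m <- matrix(as.integer(mask > 0), nrow = nrow(mask))
  new("LabelMap", labels = .cc_label(m, as.integer(connectivity)))
}

#' Remove small regions by area threshold
#'
#' Keeps every connected region whose pixel area is at least \code{S}
#' and discards the rest, then compacts the labels. With \code{S} set
#' just below the smallest plausible nucleus area this removes platelets
#' (whose area is far smaller than any leukocyte nucleus) from the
#' thresholded difference image. The boundary is inclusive: a region
#' exactly at \code{S} survives.
#'
#' @param lmap a [LabelMap-class].
#' @param S minimum area in pixels (\code{>= 0}).
#' @return a filtered [LabelMap-class].
#' @export
areaFilter <- function(lmap, S) {
  stopifnot(is(lmap, "LabelMap"), length(S) == 1, S >= 0)
  areas <- componentAreas(lmap)
  keep <- which(areas >= S)
  lab <- lmap@labels
  lab[!(lab %in% keep)] <- 0L
  LabelMap(lab)
}

#' Calibrate the platelet-removal area threshold
#'
#' Sets the area threshold to the minimum nucleus area observed in
#' ground-truth (training) data, optionally scaled by a safety factor,
#' mirroring how the empirical threshold is obtained in practice: every
#' platelet is far smaller than any nucleus, so the smallest training
#' nucleus area separates the two classes.
#'
#' @param areas numeric vector of ground-truth nucleus (or lobe) areas.
#' @param factor safety factor (default 1).
#' @return numeric threshold \code{S}.
#' @export
calibrateAreaThreshold <- function(areas, factor = 1.0) {
  if (length(areas) == 0) stop("need at least one training area")
  stopifnot(all(areas > 0), factor > 0)
  min(areas) * factor
}

#' Segment leukocyte nuclei in a micrograph
#'
#' The full segmentation stage: B-G channel difference, Otsu threshold
#' (or a fixed override), binarization, connected-component labeling and
#' the platelet area filter. A pure function of the image and the
#' parameters.
#'
#' @param img RGB array (see [loadImage()]).
#' @param params a [SegmentationParams-class]; default settings suit the
#'   default synthetic geometry.
#' @return a [LabelMap-class] of nucleus regions (lobes may still be
#'   separate regions; see [mergeLobes()]).
#' @export
segmentNuclei <- function(img, params = new("SegmentationParams")) {
  stopifnot(is(params, "SegmentationParams"))
  diff <- channelDifference(img)
  thresholdAndLabel(diff, params)$map
}

# Shared segmentation core: Otsu (or override), binarize, label, filter.
# A histogram with a single populated level has no two-class structure
# (the between-class variance is 0 for every split), so such an image is
# treated as background-only rather than all-foreground.
thresholdAndLabel <- function(diff, params) {
  hist <- grayHistogram(diff)
  t1 <- if (is.na(params@otsuOverride)) otsuThreshold(hist)
        else params@otsuOverride
  mask <- if (is.na(params@otsuOverride) && sum(hist > 0) <= 1)
    matrix(0L, nrow(diff), ncol(diff))
  else binarize(diff, t1)
  lmap <- labelComponents(mask, params@connectivity)
  list(t1 = t1, map = areaFilter(lmap, params@areaThreshold))
}
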