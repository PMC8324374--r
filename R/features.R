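## Morphological shape descriptors of a nucleus region. A "component" is
## given as its pixel coordinates: a two-column matrix with columns x
## (column index) and y (row index), as returned by componentPixels().

asPixels <- function(c) {
  if (is.matrix(c) && ncol(c) == 2 && nrow(c) >= 1) {
    colnames(c) <- c("x", "y")
    return(c)
  }
  if (is.matrix(c) && (is.logical(c) || all(c %in% c(0, 1))))
    return(maskPixels(c))
  stop("expected a two-column pixel coordinate matrix or a binary mask")
}

#' Region area
#'
#' The area of a nucleus region is its pixel count: summing an indicator
#' image over the region. No sub-pixel boundary correction is applied.
#'
#' @param c pixel coordinate matrix (columns x, y) or binary mask.
#' @return integer area in pixels.
#' @export
componentArea <- function(c) {
  px <- asPixels(c)
  nrow(px)
}

#' Tight axis-aligned bounding rectangle
#'
#' The circumscribed rectangle of a region, axis-aligned so that its
#' extents carry posture information: \code{a1} is the horizontal
#' (x / column) extent, \code{b1} the vertical (y / row) extent, both
#' inclusive pixel counts.
#'
#' @param c pixel coordinate matrix or binary mask.
#' @return list with \code{a1}, \code{b1} and \code{origin = c(x, y)}
#'   (top-left corner).
#' @export
boundingRectangle <- function(c) {
  px <- asPixels(c)
  xr <- range(px[, "x"])
  yr <- range(px[, "y"])
  list(a1 = xr[2] - xr[1] + 1L, b1 = yr[2] - yr[1] + 1L,
       origin = c(x = xr[1], y = yr[1]))
}

#' Rectangle plumpness P1
#'
#' Ratio of the region area to the area of its circumscribed rectangle,
#' \code{P1 = A / (a1 * b1)}. Always in (0, 1\]; equal to 1 exactly when
#' the region fills its bounding box (any filled axis-aligned
#' rectangle), about \code{pi/4} for a disk, and well below that for
#' scattered or curved shapes such as a multi-lobed nucleus.
#'
#' @param c pixel coordinate matrix or binary mask.
#' @return numeric P1.
#' @export
rectPlumpness <- function(c) {
  px <- asPixels(c)
  r <- boundingRectangle(px)
  nrow(px) / (as.numeric(r$a1) * as.numeric(r$b1))
}

#' Bounding-rectangle aspect ratio s
#'
#' \code{s = b1 / a1} (vertical over horizontal extent) measures the
#' posture of the region: \code{s} near 1 means a round shape or a bar
#' at 45 degrees, \code{s} far below 1 a lying shape, \code{s} far above
#' 1 an upright shape. The extents are deliberately not sorted;
#' transposing a region maps \code{s} to \code{1/s}.
#'
#' @param r a rectangle from [boundingRectangle()], or a component.
#' @return numeric aspect ratio.
#' @export
aspectRatio <- function(r) {
  if (!(is.list(r) && all(c("a1", "b1") %in% names(r))))
    r <- boundingRectangle(r)
  as.numeric(r$b1) / as.numeric(r$a1)
}

#' Moment-equivalent circumscribed ellipse
#'
#' Fits the ellipse with the same second central moments as the pixel
#' set: center at the centroid, axes from the eigen-decomposition of the
#' 2 x 2 covariance matrix of the pixel coordinates, semi-axes
#' \code{a2 = 2 * sqrt(lambda1)}, \code{b2 = 2 * sqrt(lambda2)} so that
#' an ideal filled ellipse maps to itself. The major/minor axes of this
#' ellipse are unique, which is what makes the plumpness and
#' eccentricity descriptors well defined. Degenerate regions (single
#' pixel, collinear pixels) get \code{b2} floored at 0.5 px and are
#' flagged.
#'
#' @param c pixel coordinate matrix or binary mask.
#' @return list with semi-axes \code{a2 >= b2}, \code{center},
#'   \code{orientation} (radians, major axis vs. x-axis, in
#'   (-pi/2, pi/2\]), and \code{degenerate} flag.
#' @export
fitEllipse <- function(c) {
  px <- asPixels(c)
  n <- nrow(px)
  ctr <- colMeans(px)
  if (n == 1) {
    return(list(a2 = 0.5, b2 = 0.5, center = ctr, orientation = 0,
                degenerate = TRUE))
  }
  dx <- px[, "x"] - ctr["x"]
  dy <- px[, "y"] - ctr["y"]
  cov <- matrix(c(mean(dx * dx), mean(dx * dy),
                  mean(dx * dy), mean(dy * dy)), 2, 2)
  eg <- eigen(cov, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  a2 <- 2 * sqrt(lam[1])
  b2 <- 2 * sqrt(lam[2])
  degenerate <- b2 < 0.5
  if (degenerate) b2 <- 0.5
  v <- eg$vectors[, 1]
  orientation <- atan2(v[2], v[1])
  if (orientation <= -pi / 2) orientation <- orientation + pi
  if (orientation > pi / 2) orientation <- orientation - pi
  list(a2 = a2, b2 = b2, center = ctr, orientation = orientation,
       degenerate = degenerate)
}

#' Ellipse plumpness P2
#'
#' Ratio of the region area to the area of its moment-equivalent
#' ellipse, \code{P2 = A / (pi * a2 * b2)}. Close to 1 for a filled
#' ellipse or disk; well below 1 when the region's mass sits far from an
#' elliptical fill, as for two separate lobes treated as one region.
#' Under the moment convention P2 may slightly exceed 1 for compact
#' shapes; classification thresholds absorb that.
#'
#' @param c pixel coordinate matrix or binary mask.
#' @return numeric P2, or \code{NA} with a warning for a degenerate fit.
#' @export
ellipsePlumpness <- function(c) {
  px <- asPixels(c)
  el <- fitEllipse(px)
  if (el$degenerate) {
    warning("degenerate ellipse fit; P2 undefined")
    return(NA_real_)
  }
  nrow(px) / (pi * el$a2 * el$b2)
}

#' Ellipse eccentricity e
#'
#' \code{e = sqrt(a2^2 - b2^2) / a2} of the fitted ellipse, in \[0, 1):
#' 0 for a circle, approaching 1 for a flat ellipse. Measures the
#' flatness of the nucleus region (also called its centrifugation rate).
#'
#' @param el an ellipse from [fitEllipse()], or a component.
#' @return numeric eccentricity.
#' @export
eccentricity <- function(el) {
  if (!(is.list(el) && all(c("a2", "b2") %in% names(el))))
    el <- fitEllipse(el)
  if (el$b2 > el$a2) stop("invalid ellipse: b2 > a2")
  if (el$a2 == 0) return(0)
  sqrt(el$a2^2 - el$b2^2) / el$a2
}

#' All five shape descriptors of one region
#'
#' Bundles area \code{A}, rectangle plumpness \code{P1}, aspect ratio
#' \code{s}, ellipse plumpness \code{P2} and eccentricity \code{e},
#' together with the underlying rectangle and ellipse extents. All five
#' are invariant under translation; under a 90-degree rotation
#' \code{A, P1, P2, e} are invariant and \code{s} maps to \code{1/s}.
#'
#' @param c pixel coordinate matrix or binary mask.
#' @return one-row data.frame with columns A, a1, b1, P1, s, a2, b2,
#'   P2, e, degenerate.
#' @export
featureVector <- function(c) {
  px <- asPixels(c)
  A <- nrow(px)
  r <- boundingRectangle(px)
  el <- fitEllipse(px)
  P2 <- if (el$degenerate) NA_real_ else A / (pi * el$a2 * el$b2)
  data.frame(A = A, a1 = as.integer(r$a1), b1 = as.integer(r$b1),
             P1 = A / (as.numeric(r$a1) * as.numeric(r$b1)),
             s = as.numeric(r$b1) / as.numeric(r$a1),
             a2 = el$a2, b2 = el$b2, P2 = P2,
             e = eccentricity(el), degenerate = el$degenerate)
}

#' Shape-feature table of a label map
#'
#' One row of [featureVector()] output per component, with a leading
#' \code{label} column. Suitable for export as CSV.
#'
#' @param lmap a [LabelMap-class].
#' @return data.frame with one row per component.
#' @export
shapeFeatures <- function(lmap) {
  stopifnot(is(lmap, "LabelMap"))
  n <- nComponents(lmap)
  if (n == 0L) {
    return(data.frame(label = integer(0), A = integer(0), a1 = integer(0),
                      b1 = integer(0), P1 = numeric(0), s = numeric(0),
                      a2 = numeric(0), b2 = numeric(0), P2 = numeric(0),
                      e = numeric(0), degenerate = logical(0)))
  }
  rows <- lapply(seq_len(n), function(k) {
    cbind(label = k, featureVector(componentPixels(lmap, k)))
  })
  do.call(rbind, rows)
}
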