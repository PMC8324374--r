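## Canny edge detection on binary region masks, plus the small matrix
## helpers it needs. On a binary mask the detector reduces to boundary
## extraction, which is exactly what the minimal-distance lobe merge
## needs; the full operator (Gaussian smoothing, Sobel gradients,
## non-maximum suppression, dual-threshold hysteresis) is kept so the
## same code path also works on soft masks.

# out[r, c] = m[r + dr, c + dc], zero outside.
shiftMatrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  r1 <- max(1, 1 - dr); r2 <- min(nr, nr - dr)
  c1 <- max(1, 1 - dc); c2 <- min(nc, nc - dc)
  if (r1 <= r2 && c1 <= c2)
    out[r1:r2, c1:c2] <- m[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc)]
  out
}

padReplicate <- function(m, p) {
  m[pmin(pmax(seq_len(nrow(m) + 2 * p) - p, 1), nrow(m)),
    pmin(pmax(seq_len(ncol(m) + 2 * p) - p, 1), ncol(m)), drop = FALSE]
}

# Separable correlation with a 1-D kernel (rows then columns),
# replicated edges.
convSeparable <- function(m, k) {
  p <- (length(k) - 1) / 2
  nr <- nrow(m); nc <- ncol(m)
  mp <- padReplicate(m, p)
  acc <- matrix(0, nr, nc + 2 * p)
  for (i in seq_along(k))
    acc <- acc + k[i] * mp[i:(i + nr - 1), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_along(k))
    out <- out + k[i] * acc[, i:(i + nc - 1), drop = FALSE]
  out
}

conv3x3 <- function(m, K) {
  nr <- nrow(m); nc <- ncol(m)
  mp <- padReplicate(m, 1)
  out <- matrix(0, nr, nc)
  for (i in 1:3)
    for (j in 1:3)
      out <- out + K[i, j] * mp[i:(i + nr - 1), j:(j + nc - 1), drop = FALSE]
  out
}

# Foreground pixels with a missing 4-neighbor (or on the image border).
innerBoundary <- function(fg) {
  f <- (fg > 0) * 1
  nb <- shiftMatrix(f, 1, 0) + shiftMatrix(f, -1, 0) +
    shiftMatrix(f, 0, 1) + shiftMatrix(f, 0, -1)
  f > 0 & nb < 4
}

#' Canny edge map of a binary mask
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along
#' the gradient direction and dual-threshold hysteresis (thresholds as
#' fractions of the maximal gradient magnitude). On a 0/1 mask the
#' result is a thin closed ring along the region boundary.
#'
#' @param mask binary matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @param low,high hysteresis thresholds as fractions of the maximal
#'   gradient magnitude, \code{0 < low < high <= 1}.
#' @return logical edge matrix of the same size.
#' @export
cannyEdges <- function(mask, sigma = 1.0, low = 0.1, high = 0.3) {
  assertMask(mask)
  m <- (mask > 0) * 1.0
  hw <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-hw, hw), sd = sigma)
  sm <- convSeparable(m, k / sum(k))
  Kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- conv3x3(sm, Kx)
  gy <- conv3x3(sm, t(Kx))
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  if (mx == 0) return(matrix(FALSE, nrow(mask), ncol(mask)))
  ang <- atan2(gy, gx) * 180 / pi
  ang <- ang %% 180
  sector <- integer(length(ang))
  sector[(ang >= 22.5 & ang < 67.5)] <- 1L   # diagonal down-right
  sector[(ang >= 67.5 & ang < 112.5)] <- 2L  # vertical
  sector[(ang >= 112.5 & ang < 157.5)] <- 3L # diagonal down-left
  dim(sector) <- dim(mag)
  n1 <- matrix(0, nrow(mag), ncol(mag)); n2 <- n1
  offs <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  for (s in 0:3) {
    sel <- sector == s
    if (!any(sel)) next
    o <- offs[[as.character(s)]]
    fwd <- shiftMatrix(mag, o[1], o[2])
    bwd <- shiftMatrix(mag, -o[1], -o[2])
    n1[sel] <- fwd[sel]
    n2[sel] <- bwd[sel]
  }
  keep <- mag >= n1 & mag >= n2 & mag > 0
  weak <- keep & (mag >= low * mx)
  strong <- keep & (mag >= high * mx)
  if (!any(strong)) return(strong)
  lab <- .cc_label(matrix(as.integer(weak), nrow(weak)), 8L)
  good <- unique(lab[strong])
  weak & matrix(lab %in% good, nrow(lab))
}
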