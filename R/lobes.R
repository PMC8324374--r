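#' Polylobar/unilobar decision cascade
#'
#' Applies the three-step shape cascade to each row of a feature table:
#' a region is flagged polylobar when (i) it is highly eccentric yet
#' poorly fills its moment ellipse (\code{e > x1} and \code{P2 < x2} --
#' the signature of several lobes seen as one elongated, hollow-ish
#' region), else when (ii) it poorly fills its bounding box while lying
#' flat (\code{P1 < x3} and \code{s < x4}), else when (iii) its area is
#' too small to be a whole nucleus (\code{A < x5}); otherwise it is
#' unilobar. Regions with a degenerate ellipse fit are conservatively
#' called unilobar with a warning.
#'
#' @param features data.frame from [shapeFeatures()] (or a single row
#'   from [featureVector()]).
#' @param thresholds a [LobeThresholds-class].
#' @return data.frame with columns \code{label}, \code{verdict}
#'   (\code{"polylobar"}/\code{"unilobar"}) and \code{rule}
#'   (\code{"rule2_ecc"}, \code{"rule3_rect"}, \code{"rule4_area"} or
#'   \code{"none"}).
#' @export
classifyComponents <- function(features, thresholds = new("LobeThresholds")) {
  stopifnot(is(thresholds, "LobeThresholds"))
  need <- c("A", "P1", "s", "P2", "e")
  if (!all(need %in% names(features)))
    stop("feature table must contain columns ", paste(need, collapse = ", "))
  n <- nrow(features)
  lab <- if ("label" %in% names(features)) features$label else seq_len(n)
  rule <- rep("none", n)
  deg <- if ("degenerate" %in% names(features)) features$degenerate
         else rep(FALSE, n)
  if (any(deg)) warning("degenerate features; affected regions judged unilobar")
  ok <- !deg & !is.na(features$P2)
  r2 <- ok & features$e > thresholds@x1 & features$P2 < thresholds@x2
  r3 <- ok & !r2 & features$P1 < thresholds@x3 & features$s < thresholds@x4
  r4 <- ok & !r2 & !r3 & features$A < thresholds@x5
  rule[r2] <- "rule2_ecc"
  rule[r3] <- "rule3_rect"
  rule[r4] <- "rule4_area"
  data.frame(label = lab,
             verdict = ifelse(rule == "none", "unilobar", "polylobar"),
             rule = rule, stringsAsFactors = FALSE)
}

#' Edge pixels of one region
#'
#' Canny edges of the region's binary mask, computed on a padded crop of
#' its bounding box for speed and returned as full-frame pixel
#' coordinates. Never empty: regions too small for a gradient response
#' fall back to their inner boundary pixels, and a single pixel is its
#' own edge.
#'
#' @param mask binary matrix with the region as foreground.
#' @param sigma,low,high Canny settings, see [cannyEdges()].
#' @return two-column matrix of edge pixel coordinates (x, y).
#' @export
detectEdges <- function(mask, sigma = 1.0, low = 0.1, high = 0.3) {
  assertMask(mask)
  px <- maskPixels(mask)
  if (nrow(px) == 0) stop("empty region has no edges")
  if (nrow(px) == 1) return(px)
  pad <- max(2L, ceiling(3 * sigma)) + 1L
  x1 <- max(1L, min(px[, "x"]) - pad); x2 <- min(ncol(mask), max(px[, "x"]) + pad)
  y1 <- max(1L, min(px[, "y"]) - pad); y2 <- min(nrow(mask), max(px[, "y"]) + pad)
  crop <- (mask[y1:y2, x1:x2, drop = FALSE] > 0) * 1L
  edges <- cannyEdges(crop, sigma, low, high)
  if (!any(edges)) edges <- innerBoundary(crop)
  e <- maskPixels(edges)
  cbind(x = e[, "x"] + x1 - 1L, y = e[, "y"] + y1 - 1L)
}

#' Minimal distance between two edge-pixel sets
#'
#' Euclidean distance minimised over all pixel pairs, with the attaining
#' pair returned. Ties are broken by row-major order of the first
#' point's pixel, then the second's, so the result is deterministic.
#'
#' @param ea,eb two-column coordinate matrices (columns x, y).
#' @return list with \code{d} (pixels), \code{pa}, \code{pb}
#'   (named x/y vectors).
#' @export
minPairDistance <- function(ea, eb) {
  if (!is.matrix(ea) || nrow(ea) == 0 || !is.matrix(eb) || nrow(eb) == 0)
    stop("both edge sets must be non-empty coordinate matrices")
  dx <- outer(ea[, 1], eb[, 1], "-")
  dy <- outer(ea[, 2], eb[, 2], "-")
  d2 <- dx * dx + dy * dy
  dmin <- min(d2)
  hits <- which(d2 == dmin, arr.ind = TRUE)
  key <- order(ea[hits[, 1], 2], ea[hits[, 1], 1],
               eb[hits[, 2], 2], eb[hits[, 2], 1])[1]
  i <- hits[key, 1]; j <- hits[key, 2]
  list(d = sqrt(dmin),
       pa = c(x = unname(ea[i, 1]), y = unname(ea[i, 2])),
       pb = c(x = unname(eb[j, 1]), y = unname(eb[j, 2])))
}

# Integer pixels of the digital straight line from p0 to p1 (Bresenham).
bresenhamLine <- function(p0, p1) {
  x0 <- as.integer(p0[1]); y0 <- as.integer(p0[2])
  x1 <- as.integer(p1[1]); y1 <- as.integer(p1[2])
  dx <- abs(x1 - x0); dy <- -abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx + dy
  xs <- integer(0); ys <- integer(0)
  repeat {
    xs <- c(xs, x0); ys <- c(ys, y0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2L * err
    if (e2 >= dy) { err <- err + dy; x0 <- x0 + sx }
    if (e2 <= dx) { err <- err + dx; y0 <- y0 + sy }
  }
  cbind(x = xs, y = ys)
}

# Fill background regions fully enclosed by (and adjacent only to) the
# component of `mask` containing the pixel `at` (x, y).
fillComponentHoles <- function(mask, at) {
  m <- (mask > 0) * 1L
  lab <- .cc_label(m, 8L)
  target <- lab[at[2], at[1]]
  if (target == 0) return(m)
  bg <- matrix(as.integer(lab == 0), nrow(m))
  labBg <- .cc_label(bg, 4L)
  nr <- nrow(m); nc <- ncol(m)
  borderLabs <- unique(c(labBg[1, ], labBg[nr, ], labBg[, 1], labBg[, nc]))
  holeLabs <- setdiff(unique(labBg[labBg > 0]), borderLabs)
  for (h in holeLabs) {
    hm <- labBg == h
    nb <- unique(c(shiftMatrix(lab, 1, 0)[hm], shiftMatrix(lab, -1, 0)[hm],
                   shiftMatrix(lab, 0, 1)[hm], shiftMatrix(lab, 0, -1)[hm]))
    nb <- nb[nb > 0]
    if (length(nb) && all(nb == target)) m[hm] <- 1L
  }
  m
}

#' Connect two points in a mask and fill the joined region
#'
#' Draws the digital straight line between \code{pa} and \code{pb}
#' (setting those pixels to foreground) and then fills any interior
#' holes of the resulting connected region, so that two joined lobes --
#' possibly forming a closed ring with the new bridge -- become one
#' solid region.
#'
#' @param mask binary matrix.
#' @param pa,pb endpoints as (x, y) vectors inside the mask bounds.
#' @return integer 0/1 matrix.
#' @export
connectPair <- function(mask, pa, pb) {
  assertMask(mask)
  for (p in list(pa, pb))
    if (p[1] < 1 || p[1] > ncol(mask) || p[2] < 1 || p[2] > nrow(mask))
      stop("endpoint out of mask bounds")
  m <- (mask > 0) * 1L
  line <- bresenhamLine(pa, pb)
  m[cbind(line[, "y"], line[, "x"])] <- 1L
  fillComponentHoles(m, pa)
}

# Row-major key of a component: its first pixel in a row-major scan,
# which survives relabeling and identifies a region across merge steps.
componentKey <- function(lmap, label) {
  px <- componentPixels(lmap, label)
  i <- order(px[, "y"], px[, "x"])[1]
  sprintf("%d:%d", px[i, "y"], px[i, "x"])
}

#' Merge disconnected nucleus lobes by the minimal-distance rule
#'
#' Iteratively re-joins regions flagged as polylobar candidates: the
#' first (row-major) unprocessed candidate is paired with its nearest
#' region by minimal Canny-edge distance, and the pair is connected and
#' filled when (a) the distance is within the cap (absolute
#' \code{dMax}, or \code{dMaxFactor} times the equivalent diameter
#' \code{2*sqrt(A/pi)} of the larger region), (b) the partner is itself
#' a polylobar candidate -- unilobar nuclei are never absorbed -- and
#' (c) the merged area stays below \code{aMax}. After every merge the
#' shape features and the cascade verdicts are recomputed, so a merged
#' region that now looks like a whole nucleus stops attracting further
#' merges. The loop ends when every candidate has been processed; the
#' component count never increases and drops by exactly one per accepted
#' merge.
#'
#' @param lmap a [LabelMap-class] (after platelet filtering).
#' @param thresholds a [LobeThresholds-class] for (re-)classification.
#' @param params a [MergeParams-class].
#' @param connectivity region connectivity used while relabeling
#'   (default 8).
#' @return list with \code{map} (the merged [LabelMap-class]),
#'   \code{decisions} (final per-region decision data.frame) and
#'   \code{nMerges}.
#' @export
mergeLobes <- function(lmap, thresholds = new("LobeThresholds"),
                       params = new("MergeParams"), connectivity = 8L) {
  stopifnot(is(lmap, "LabelMap"), is(thresholds, "LobeThresholds"),
            is(params, "MergeParams"))
  mask <- (labelMatrix(lmap) > 0) * 1L
  processed <- character(0)
  nMerges <- 0L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > params@maxIterations + nMerges)
      stop("lobe merging did not terminate within maxIterations")
    lm <- labelComponents(mask, connectivity)
    n <- nComponents(lm)
    feats <- shapeFeatures(lm)
    dec <- classifyComponents(feats, thresholds)
    if (n == 0L) break
    keys <- vapply(seq_len(n), function(k) componentKey(lm, k), character(1))
    cand <- which(dec$verdict == "polylobar" & !(keys %in% processed))
    if (length(cand) == 0L) break
    k <- cand[1]
    if (n == 1L) { processed <- c(processed, keys[k]); next }
    edges <- lapply(seq_len(n), function(j)
      detectEdges(componentMask(lm, j), params@cannySigma,
                  params@cannyLow, params@cannyHigh))
    others <- setdiff(seq_len(n), k)
    dists <- lapply(others, function(j) minPairDistance(edges[[k]], edges[[j]]))
    dd <- vapply(dists, `[[`, numeric(1), "d")
    best <- which.min(dd)             # first minimum = smallest label
    j <- others[best]
    areas <- feats$A
    dCap <- if (!is.na(params@dMax)) params@dMax else
      params@dMaxFactor * 2 * sqrt(max(areas[k], areas[j]) / pi)
    accept <- dd[best] <= dCap &&
      dec$verdict[j] == "polylobar" &&
      areas[k] + areas[j] <= params@aMax
    if (accept) {
      mask <- connectPair(mask, dists[[best]]$pa, dists[[best]]$pb)
      processed <- setdiff(processed, keys[c(k, j)])
      nMerges <- nMerges + 1L
    } else {
      processed <- c(processed, keys[k])
    }
  }
  list(map = lm, decisions = dec, nMerges = nMerges)
}
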