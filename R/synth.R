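## Synthetic Wright-stain-like blood smear generator with ground truth.
## The renderer paints flat colors (background, then erythrocytes, then
## platelets, then nuclei), so nucleus and platelet pixels always carry
## exactly their configured color and the B-G separation between
## foreground and background classes holds by construction.

# Conservative bounding radius of a cell, used for overlap checks and
# in-bounds placement.
cellExtentRadius <- function(cell) {
  r <- as.numeric(cell$lobeRadius)
  if (cell$type == "unilobar") return(r + 2)
  k <- as.integer(cell$lobeCount)
  gap <- as.numeric(cell$gap)
  spacing <- 2 * r * 1.04 + gap
  ((k - 1) / 2) * spacing + r * 1.04 + 3
}

#' Construct a synthetic smear specification
#'
#' Convenience constructor for [SmearSpec-class]; see that class for the
#' cell-list format. Defaults give a 256 x 256 image whose colors keep
#' nucleus/platelet pixels at a B-G difference of 80-100 gray levels
#' against a background/erythrocyte B-G of at most 10.
#'
#' @param width,height image size in pixels.
#' @param cells list of cell specifications.
#' @param seed RNG seed for rendering.
#' @param erythrocyteCount,plateletCount scene composition.
#' @param ... further slots of [SmearSpec-class] (colors, ranges).
#' @return a [SmearSpec-class].
#' @export
smearSpec <- function(width = 256L, height = 256L, cells = list(),
                      seed = 1L, erythrocyteCount = 6L, plateletCount = 4L,
                      ...) {
  new("SmearSpec", width = as.integer(width), height = as.integer(height),
      cells = cells, seed = as.integer(seed),
      erythrocyteCount = as.integer(erythrocyteCount),
      plateletCount = as.integer(plateletCount), ...)
}

# Logical mask of a (rotated) filled ellipse on an h x w grid.
ellipseMask <- function(h, w, cx, cy, a, b, theta = 0) {
  X <- matrix(seq_len(w), h, w, byrow = TRUE)
  Y <- matrix(seq_len(h), h, w)
  dx <- X - cx; dy <- Y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# Logical mask of a thick segment (all pixels within `halfWidth` of the
# segment p0-p1).
segmentMask <- function(h, w, p0, p1, halfWidth = 1.0) {
  X <- matrix(seq_len(w), h, w, byrow = TRUE)
  Y <- matrix(seq_len(h), h, w)
  vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
  len2 <- vx * vx + vy * vy
  if (len2 == 0) return(((X - p0[1])^2 + (Y - p0[2])^2) <= halfWidth^2)
  t <- ((X - p0[1]) * vx + (Y - p0[2]) * vy) / len2
  t[t < 0] <- 0; t[t > 1] <- 1
  qx <- p0[1] + t * vx; qy <- p0[2] + t * vy
  ((X - qx)^2 + (Y - qy)^2) <= halfWidth^2
}

paintMask <- function(img, mask, color) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- as.integer(color[ch])
    img[, , ch] <- plane
  }
  img
}

# Render one cell's nucleus mask. Lobes of a polylobar cell are laid
# out along a straight chain in direction `angle` with slight
# perpendicular jitter; the three connection modes differ in the
# edge-to-edge gap sign and in whether thin bridges are drawn.
renderCellMask <- function(h, w, cell) {
  r <- as.numeric(cell$lobeRadius)
  ang <- as.numeric(cell$angle %||% 0)
  cx <- cell$center[1]; cy <- cell$center[2]
  if (cell$type == "unilobar") {
    ar <- as.numeric(cell$axisRatio %||% 1.15)
    return(ellipseMask(h, w, cx, cy, r, r / ar, ang))
  }
  k <- as.integer(cell$lobeCount)
  gap <- as.numeric(cell$gap)
  radii <- r * stats::runif(k, 0.96, 1.04)
  u <- c(cos(ang), sin(ang)); vperp <- c(-sin(ang), cos(ang))
  pos <- matrix(0, k, 2)
  for (i in seq_len(k)[-1])
    pos[i, ] <- pos[i - 1, ] + (radii[i - 1] + radii[i] + gap) * u
  pos <- pos + matrix(stats::runif(k, -1, 1), k, 1) %*% rbind(vperp)
  pos <- sweep(pos, 2, colMeans(pos) - c(cx, cy), "-")
  mask <- matrix(FALSE, h, w)
  for (i in seq_len(k))
    mask <- mask | ellipseMask(h, w, pos[i, 1], pos[i, 2], radii[i], radii[i])
  if (identical(cell$connection, "filament")) {
    for (i in seq_len(k)[-1])
      mask <- mask | segmentMask(h, w, pos[i - 1, ], pos[i, ], 1.0)
  }
  mask
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a synthetic smear image with ground truth
#'
#' Draws the scene described by a [SmearSpec-class]: light background,
#' pink erythrocytes (with B close to G, so they vanish from the
#' channel-difference image just as they do under Wright's staining),
#' small platelet blobs, and one nucleus per cell -- unilobar, or 2-5
#' lobes that are filament-connected, overlapping, or completely
#' disconnected. Platelets are placed away from nuclei so the scene
#' stays unambiguous. Rendering is deterministic given the spec
#' (including its seed).
#'
#' @param spec a [SmearSpec-class].
#' @return list with \code{image} (RGB array) and \code{truth}
#'   (a [SmearTruth-class]).
#' @export
makeCellImage <- function(spec) {
  stopifnot(is(spec, "SmearSpec"))
  validObject(spec)
  h <- spec@height; w <- spec@width
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(spec@seed)

  img <- array(0L, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- as.integer(spec@background[ch])

  for (i in seq_len(spec@erythrocyteCount)) {
    r <- stats::runif(1, spec@erythrocyteRadius[1], spec@erythrocyteRadius[2])
    cx <- stats::runif(1, r + 1, w - r)
    cy <- stats::runif(1, r + 1, h - r)
    img <- paintMask(img, ellipseMask(h, w, cx, cy, r, r * 0.92,
                                      stats::runif(1, 0, pi)),
                     spec@erythrocyteColor)
  }

  exts <- vapply(spec@cells, cellExtentRadius, numeric(1))
  ctrs <- if (length(spec@cells))
    t(vapply(spec@cells, function(cl) as.numeric(cl$center), numeric(2)))
  else matrix(0, 0, 2)

  plateletMask <- matrix(FALSE, h, w)
  placed <- matrix(0, 0, 3)             # cx, cy, r
  for (i in seq_len(spec@plateletCount)) {
    A <- stats::runif(1, spec@plateletArea[1], spec@plateletArea[2])
    r <- sqrt(A / pi)
    for (try in 1:300) {
      cx <- stats::runif(1, r + 3, w - r - 2)
      cy <- stats::runif(1, r + 3, h - r - 2)
      clear <- TRUE
      if (length(exts))
        clear <- all(sqrt((ctrs[, 1] - cx)^2 + (ctrs[, 2] - cy)^2) >
                       exts + r + 6)
      if (clear && nrow(placed))
        clear <- all(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) >
                       placed[, 3] + r + 3)
      if (clear) break
    }
    if (!clear) next
    placed <- rbind(placed, c(cx, cy, r))
    plateletMask <- plateletMask | ellipseMask(h, w, cx, cy, r, r)
  }
  img <- paintMask(img, plateletMask, spec@plateletColor)

  masks <- vector("list", length(spec@cells))
  for (i in seq_along(spec@cells)) {
    masks[[i]] <- renderCellMask(h, w, spec@cells[[i]])
    img <- paintMask(img, masks[[i]], spec@nucleusColor)
  }
  nucleusUnion <- Reduce(`|`, masks, matrix(FALSE, h, w))
  plateletMask <- plateletMask & !nucleusUnion

  types <- vapply(spec@cells, function(cl)
    as.character(cl$cellType %||% "N"), character(1))
  lobar <- vapply(spec@cells, function(cl) cl$type, character(1))
  truth <- new("SmearTruth", masks = masks, types = types, lobar = lobar,
               plateletMask = plateletMask,
               cellCount = length(masks))
  list(image = img, truth = truth)
}

# Draw the geometry of one cell of a given class. Assumes the RNG is
# already seeded by the caller. Polylobar lobes are sized so a single
# lobe sits between the platelet area threshold S (150 px) and the
# whole-nucleus area scale (cascade threshold x5 = 250 px); unilobar
# nuclei are several times larger.
sampleCellGeometry <- function(cellType) {
  if (cellType %in% c("B", "M", "L")) {
    r <- switch(cellType,
                B = stats::runif(1, 14, 17),
                M = stats::runif(1, 18, 22),
                L = stats::runif(1, 14, 18))
    return(list(type = "unilobar", lobeCount = 1L, lobeRadius = r,
                gap = 0, connection = "none",
                axisRatio = stats::runif(1, 1.0, 1.3),
                angle = stats::runif(1, 0, pi), cellType = cellType))
  }
  lobeCount <- if (cellType == "E") 2L else
    sample(2:5, 1, prob = c(0.25, 0.35, 0.25, 0.15))
  connection <- if (cellType == "E")
    sample(c("overlap", "filament", "disconnected"), 1,
           prob = c(0.4, 0.4, 0.2))
  else
    sample(c("filament", "overlap", "disconnected"), 1,
           prob = c(0.35, 0.25, 0.40))
  r <- stats::runif(1, 7.2, 8.4)
  gap <- switch(connection,
                disconnected = stats::runif(1, 0.70, 0.92) * r,
                filament = stats::runif(1, 0.30, 0.50) * r,
                overlap = -stats::runif(1, 0.40, 0.70) * r)
  list(type = "polylobar", lobeCount = lobeCount, lobeRadius = r,
       gap = gap, connection = connection,
       angle = stats::runif(1, 0, pi), cellType = cellType)
}

placeCellsOnLine <- function(cells, w, h, edgeGap) {
  exts <- vapply(cells, cellExtentRadius, numeric(1))
  stopifnot(length(cells) == 2)
  for (try in 1:100) {
    phi <- stats::runif(1, 0, pi)
    d <- exts[1] + exts[2] + edgeGap
    cx <- w / 2 + stats::runif(1, -15, 15)
    cy <- h / 2 + stats::runif(1, -15, 15)
    p1 <- c(cx, cy) - d / 2 * c(cos(phi), sin(phi))
    p2 <- c(cx, cy) + d / 2 * c(cos(phi), sin(phi))
    ok <- all(p1 > exts[1] + 2) && all(p2 > exts[2] + 2) &&
      p1[1] < w - exts[1] - 2 && p1[2] < h - exts[1] - 2 &&
      p2[1] < w - exts[2] - 2 && p2[2] < h - exts[2] - 2
    if (ok) break
  }
  cells[[1]]$center <- p1
  cells[[2]]$center <- p2
  cells
}

#' Misjudgment-prone scene presets
#'
#' Four scene archetypes that historically cause leukocyte miscounts,
#' each with a known ground-truth count: (1) a single polylobar nucleus
#' whose three disconnected lobes require repeated minimal-distance
#' connection (true count 1); (2) two nearby unilobar cells that must
#' not be merged (2); (3) one unilobar plus one two-lobed polylobar
#' nucleus at similar distances (2); (4) two polylobar nuclei whose
#' internal lobe gaps are small but whose mutual distance is large (2).
#'
#' @param k preset number, 1-4.
#' @param seed RNG seed controlling the randomised geometry.
#' @return a [SmearSpec-class].
#' @export
casePreset <- function(k, seed = 1L) {
  if (!k %in% 1:4) stop("preset number must be 1, 2, 3 or 4")
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv())
  })
  presetSeed <- (as.integer(seed) %% 1000003L) + 7919L * as.integer(k)
  set.seed(presetSeed)
  w <- 256L; h <- 256L
  if (k == 1) {
    cell <- sampleCellGeometry("N")
    cell$lobeCount <- 3L
    cell$connection <- "disconnected"
    cell$gap <- stats::runif(1, 0.70, 0.92) * cell$lobeRadius
    ext <- cellExtentRadius(cell)
    cell$center <- c(stats::runif(1, ext + 3, w - ext - 3),
                     stats::runif(1, ext + 3, h - ext - 3))
    cells <- list(cell)
  } else if (k == 2) {
    cells <- list(sampleCellGeometry(sample(c("B", "M", "L"), 1)),
                  sampleCellGeometry(sample(c("B", "M", "L"), 1)))
    cells <- placeCellsOnLine(cells, w, h, stats::runif(1, 10, 16))
  } else if (k == 3) {
    poly <- sampleCellGeometry("N")
    poly$lobeCount <- 2L
    poly$connection <- "disconnected"
    poly$gap <- stats::runif(1, 0.70, 0.92) * poly$lobeRadius
    cells <- list(sampleCellGeometry(sample(c("M", "L"), 1)), poly)
    cells <- placeCellsOnLine(cells, w, h, stats::runif(1, 16, 22))
  } else {
    mk <- function() {
      cl <- sampleCellGeometry("N")
      cl$lobeCount <- 2L
      cl$connection <- "disconnected"
      cl$gap <- stats::runif(1, 0.70, 0.92) * cl$lobeRadius
      cl
    }
    cells <- placeCellsOnLine(list(mk(), mk()), w, h,
                              stats::runif(1, 26, 34))
  }
  smearSpec(width = w, height = h, cells = cells,
            seed = presetSeed,
            erythrocyteCount = sample(4:8, 1),
            plateletCount = sample(2:5, 1))
}

#' Generate a reproducible synthetic dataset
#'
#' Renders \code{n} single-cell smear images whose cell classes follow
#' the given mix (default: 113 neutrophils, 36 eosinophils, 18
#' basophils, 69 monocytes and 64 lymphocytes per 300 images, the
#' composition of a typical differential-count evaluation set).
#' Neutrophils are polylobar with 2-5 lobes and a random connection
#' mode, eosinophils two-lobed, and the remaining classes unilobar.
#' Per-image RNG substreams are drawn once from the dataset seed, so the
#' first \code{n} images of a longer run are identical to a shorter run.
#'
#' @param n number of images.
#' @param mix named proportions or counts for classes N, E, B, M, L.
#' @param seed dataset seed.
#' @return list of \code{list(image, truth)} pairs.
#' @export
makeDataset <- function(n,
                        mix = c(N = 113, E = 36, B = 18, M = 69, L = 64),
                        seed = 1L) {
  stopifnot(n >= 1)
  if (is.null(names(mix)) || !setequal(names(mix), c("N", "E", "B", "M", "L")))
    stop("mix must be named with classes N, E, B, M, L")
  if (any(mix < 0) || sum(mix) <= 0) stop("invalid class proportions")
  p <- mix[c("N", "E", "B", "M", "L")] / sum(mix)
  # balanced sequence: image i's class maximizes the running deficit
  # p*i - assigned, so the class sequence depends only on the index and
  # the mix -- a longer run shares its prefix with a shorter one, and
  # counts track the quotas (exactly when n is a multiple of the mix).
  assigned <- stats::setNames(numeric(5), names(p))
  types <- character(n)
  for (i in seq_len(n)) {
    deficit <- p * i - assigned
    pick <- names(p)[order(-deficit, -p)[1]]
    assigned[pick] <- assigned[pick] + 1
    types[i] <- pick
  }

  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  subSeeds <- sample.int(.Machine$integer.max - 1L, n)

  lapply(seq_len(n), function(i) {
    set.seed(subSeeds[i])
    cell <- sampleCellGeometry(types[i])
    w <- 256L; h <- 256L
    ext <- cellExtentRadius(cell)
    cell$center <- c(stats::runif(1, ext + 4, w - ext - 4),
                     stats::runif(1, ext + 4, h - ext - 4))
    spec <- smearSpec(width = w, height = h, cells = list(cell),
                      seed = subSeeds[i],
                      erythrocyteCount = sample(4:8, 1),
                      plateletCount = sample(2:6, 1))
    makeCellImage(spec)
  })
}
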