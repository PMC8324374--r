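#' @useDynLib LeukoLobes, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' Label map of segmented nucleus regions
#'
#' An integer matrix the size of the source image in which 0 marks
#' background and each connected foreground region carries a positive
#' label. Labels are always the compact set \code{1..n} assigned in
#' row-major first-encounter order, so a \code{LabelMap} built twice from
#' the same mask is identical.
#'
#' @slot labels integer matrix, 0 = background, k = k-th component met in
#'   a row-major scan.
#' @seealso [labelComponents()], [areaFilter()], [segmentNuclei()]
#' @export
setClass("LabelMap", representation(labels = "matrix"))

setValidity("LabelMap", function(object) {
  lab <- object@labels
  if (length(lab) == 0) return("labels matrix is empty")
  if (anyNA(lab)) return("labels must not contain NA")
  if (any(lab < 0)) return("labels must be non-negative")
  if (any(lab != floor(lab))) return("labels must be integers")
  n <- max(lab)
  if (n > 0) {
    present <- sort(unique(lab[lab > 0]))
    if (!identical(as.integer(present), seq_len(n)))
      return("labels must be the compact set 1..n")
  }
  TRUE
})

#' Segmentation parameters
#'
#' Settings of the nucleus segmentation stage: the Otsu threshold can be
#' overridden with a fixed gray level, platelets are removed by the area
#' threshold \code{S} (a connected region survives iff its pixel area is
#' \code{>= S}), and region connectivity is 4 or 8.
#'
#' @slot otsuOverride numeric, fixed gray threshold in \[0, 255\] or
#'   \code{NA} to let Otsu's method pick it per image.
#' @slot areaThreshold numeric, minimum region area \code{S} in pixels.
#'   The default (150) is calibrated for the default synthetic geometry;
#'   for real data use [calibrateAreaThreshold()].
#' @slot connectivity integer, 4 or 8 (default 8 so that thin diagonal
#'   chromatin filaments do not fracture a nucleus).
#' @export
setClass("SegmentationParams",
         representation(otsuOverride = "numeric",
                        areaThreshold = "numeric",
                        connectivity = "integer"),
         prototype(otsuOverride = NA_real_,
                   areaThreshold = 150,
                   connectivity = 8L))

setValidity("SegmentationParams", function(object) {
  if (length(object@otsuOverride) != 1) return("otsuOverride must be length 1")
  if (!is.na(object@otsuOverride) &&
      (object@otsuOverride < 0 || object@otsuOverride > 255))
    return("otsuOverride must be in [0, 255] or NA")
  if (length(object@areaThreshold) != 1 || is.na(object@areaThreshold) ||
      object@areaThreshold < 0)
    return("areaThreshold must be a single value >= 0")
  if (!object@connectivity %in% c(4L, 8L))
    return("connectivity must be 4 or 8")
  TRUE
})

#' Polylobar decision-cascade thresholds
#'
#' The five empirical thresholds of the shape cascade that flags a
#' segmented region as part of a polylobar nucleus. A region is a
#' polylobar candidate when (i) eccentricity \code{e > x1} and ellipse
#' plumpness \code{P2 < x2}, else (ii) rectangle plumpness \code{P1 < x3}
#' and aspect ratio \code{s < x4}, else (iii) area \code{A < x5};
#' otherwise it is unilobar.
#'
#' Defaults are calibrated against the default synthetic smear geometry
#' (see the package vignette); [calibrateThresholds()] re-derives them
#' from labeled feature tables.
#'
#' @slot x1 eccentricity threshold in \[0, 1).
#' @slot x2 ellipse-plumpness threshold (> 0).
#' @slot x3 rectangle-plumpness threshold (> 0).
#' @slot x4 aspect-ratio threshold (> 0).
#' @slot x5 area threshold in pixels (>= 1).
#' @export
setClass("LobeThresholds",
         representation(x1 = "numeric", x2 = "numeric", x3 = "numeric",
                        x4 = "numeric", x5 = "numeric"),
         prototype(x1 = 0.90, x2 = 0.78, x3 = 0.55, x4 = 0.80, x5 = 250))

setValidity("LobeThresholds", function(object) {
  v <- c(object@x1, object@x2, object@x3, object@x4, object@x5)
  if (length(v) != 5 || anyNA(v)) return("all five thresholds must be set")
  if (object@x1 < 0 || object@x1 >= 1) return("x1 must be in [0, 1)")
  if (object@x2 <= 0) return("x2 must be > 0")
  if (object@x3 <= 0) return("x3 must be > 0")
  if (object@x4 <= 0) return("x4 must be > 0")
  if (object@x5 < 1) return("x5 must be >= 1")
  TRUE
})

#' Lobe-merging parameters
#'
#' Controls of the minimal-distance merge that re-joins disconnected
#' lobes of one nucleus. A candidate pair is merged only when the minimal
#' edge-to-edge distance is within the cap, both regions are polylobar
#' candidates, and the merged area stays plausible for a single nucleus.
#'
#' @slot dMax numeric, absolute distance cap in pixels, or \code{NA} to
#'   use the relative rule \code{dMaxFactor * } equivalent diameter
#'   \code{2*sqrt(A/pi)} of the larger region of the pair.
#' @slot dMaxFactor numeric, factor of the relative distance rule
#'   (default 0.6: lobe gaps are small relative to nucleus size,
#'   inter-cell gaps are not).
#' @slot aMax numeric, maximal plausible single-nucleus area in pixels;
#'   merges that would exceed it are rejected.
#' @slot maxIterations integer, safety cap on merge-loop iterations.
#' @slot cannySigma,cannyLow,cannyHigh numeric, Canny edge-detector
#'   settings (Gaussian sigma in pixels; hysteresis thresholds as
#'   fractions of the maximal gradient magnitude). On binary masks the
#'   detector reduces to boundary extraction, so these are not sensitive.
#' @export
setClass("MergeParams",
         representation(dMax = "numeric", dMaxFactor = "numeric",
                        aMax = "numeric", maxIterations = "integer",
                        cannySigma = "numeric", cannyLow = "numeric",
                        cannyHigh = "numeric"),
         prototype(dMax = NA_real_, dMaxFactor = 0.6, aMax = 2500,
                   maxIterations = 100L, cannySigma = 1.0,
                   cannyLow = 0.1, cannyHigh = 0.3))

setValidity("MergeParams", function(object) {
  if (!is.na(object@dMax) && object@dMax <= 0) return("dMax must be > 0 or NA")
  if (is.na(object@dMaxFactor) || object@dMaxFactor <= 0)
    return("dMaxFactor must be > 0")
  if (is.na(object@aMax) || object@aMax <= 0) return("aMax must be > 0")
  if (object@maxIterations < 1L) return("maxIterations must be >= 1")
  if (object@cannySigma <= 0) return("cannySigma must be > 0")
  if (object@cannyLow <= 0 || object@cannyHigh <= object@cannyLow ||
      object@cannyHigh > 1)
    return("need 0 < cannyLow < cannyHigh <= 1")
  TRUE
})

#' Full pipeline parameters
#'
#' Bundles the segmentation, classification and merging settings consumed
#' by [analyzeSmear()]. The merge-loop area cap must exceed the cascade's
#' small-area threshold \code{x5}, otherwise regions flagged polylobar by
#' area alone could never legally merge.
#'
#' @slot segmentation a [SegmentationParams-class] object.
#' @slot thresholds a [LobeThresholds-class] object.
#' @slot merge a [MergeParams-class] object.
#' @export
setClass("PipelineParams",
         representation(segmentation = "SegmentationParams",
                        thresholds = "LobeThresholds",
                        merge = "MergeParams"),
         prototype(segmentation = new("SegmentationParams"),
                   thresholds = new("LobeThresholds"),
                   merge = new("MergeParams")))

setValidity("PipelineParams", function(object) {
  if (object@merge@aMax <= object@thresholds@x5)
    return("merge aMax must exceed the cascade area threshold x5")
  TRUE
})

#' Leukocyte count report
#'
#' Final counts for one micrograph: the total number of leukocytes
#' \code{T} (connected nucleus regions after lobe merging), the
#' polylobar/unilobar split, and per-type tallies
#' (N = neutrophil, E = eosinophil, B = basophil, M = monocyte,
#' L = lymphocyte). Per-type tallies are only populated when ground-truth
#' cell types are supplied; their sum must then equal \code{T} -- a
#' per-type sum exceeding \code{T} is an inconsistency and is refused.
#'
#' @slot total integer, total leukocyte count T.
#' @slot polylobar integer, regions judged polylobar.
#' @slot unilobar integer, regions judged unilobar.
#' @slot perType named integer vector \code{c(N=, E=, B=, M=, L=)}.
#' @export
setClass("CountReport",
         representation(total = "integer", polylobar = "integer",
                        unilobar = "integer", perType = "integer"),
         prototype(total = 0L, polylobar = 0L, unilobar = 0L,
                   perType = c(N = 0L, E = 0L, B = 0L, M = 0L, L = 0L)))

setValidity("CountReport", function(object) {
  if (object@total < 0L) return("total must be >= 0")
  if (object@polylobar + object@unilobar != object@total)
    return("polylobar + unilobar must equal total")
  pt <- object@perType
  if (!identical(names(pt), c("N", "E", "B", "M", "L")))
    return("perType must be named N, E, B, M, L")
  if (any(pt < 0L)) return("perType counts must be >= 0")
  s <- sum(pt)
  if (s > object@total)
    return("per-type counts exceed the total T; counting stopped")
  if (s > 0L && s != object@total)
    return("populated per-type counts must sum to total T")
  TRUE
})

#' Segmentation-accuracy evaluation result
#'
#' Per-class and pooled counting accuracy over a set of images. An image
#' counts as correct when the predicted leukocyte count equals the
#' ground-truth count and predicted regions match ground-truth nuclei
#' one-to-one by majority pixel overlap. The pooled accuracy is
#' \code{sum(correct)/sum(samples)}, never the mean of class accuracies.
#'
#' @slot perClass data.frame with columns \code{class}, \code{n},
#'   \code{correct}, \code{accuracy} (percent).
#' @slot overall numeric, pooled accuracy in percent.
#' @export
setClass("EvalResult",
         representation(perClass = "data.frame", overall = "numeric"))

setValidity("EvalResult", function(object) {
  pc <- object@perClass
  need <- c("class", "n", "correct", "accuracy")
  if (!all(need %in% names(pc))) return("perClass must have class/n/correct/accuracy")
  if (any(pc$correct > pc$n)) return("correct must be <= n")
  TRUE
})

#' Synthetic blood-smear specification
#'
#' Describes one synthetic Wright-stain-like micrograph: a light
#' background, pink erythrocytes (invisible to the B-G channel
#' difference), small dark platelets, and leukocyte nuclei that are
#' either unilobar or split into 2-5 lobes connected by thin filaments,
#' by overlap, or not at all. Colors are parameterised but must keep the
#' B-G separation between nucleus/platelet pixels and
#' background/erythrocyte pixels that makes Otsu segmentation well posed.
#'
#' Cells are given as a list of lists with fields \code{type}
#' (\code{"unilobar"} or \code{"polylobar"}), \code{lobeCount} (1, or
#' 2-5), \code{lobeRadius} (pixels), \code{gap} (edge-to-edge lobe gap,
#' pixels, disconnected mode), \code{connection} (\code{"filament"},
#' \code{"overlap"}, \code{"disconnected"}; unilobar cells use
#' \code{"none"}), \code{center} (x, y), \code{angle} (chain direction,
#' radians) and optional \code{cellType} (one of N/E/B/M/L).
#'
#' @slot width,height image size in pixels.
#' @slot background,nucleusColor,plateletColor,erythrocyteColor RGB
#'   triples in \[0, 255\].
#' @slot erythrocyteCount,plateletCount integer counts.
#' @slot erythrocyteRadius numeric length-2 range, pixels.
#' @slot plateletArea numeric length-2 range, pixels.
#' @slot cells list of per-cell specifications (see Details).
#' @slot seed integer RNG seed; rendering is deterministic given the spec.
#' @export
setClass("SmearSpec",
         representation(width = "integer", height = "integer",
                        background = "numeric", nucleusColor = "numeric",
                        plateletColor = "numeric",
                        erythrocyteColor = "numeric",
                        erythrocyteCount = "integer",
                        erythrocyteRadius = "numeric",
                        plateletCount = "integer", plateletArea = "numeric",
                        cells = "list", seed = "integer"),
         prototype(width = 256L, height = 256L,
                   background = c(235, 225, 230),
                   nucleusColor = c(95, 60, 160),
                   plateletColor = c(120, 85, 165),
                   erythrocyteColor = c(230, 180, 190),
                   erythrocyteCount = 6L,
                   erythrocyteRadius = c(12, 18),
                   plateletCount = 4L, plateletArea = c(20, 60),
                   cells = list(), seed = 1L))

setValidity("SmearSpec", function(object) {
  if (object@width < 32L || object@height < 32L)
    return("image must be at least 32x32")
  cols <- rbind(object@background, object@nucleusColor,
                object@plateletColor, object@erythrocyteColor)
  if (any(cols < 0) || any(cols > 255)) return("colors must be in [0, 255]")
  bgDiff <- max(object@background[3] - object@background[2],
                object@erythrocyteColor[3] - object@erythrocyteColor[2], 0)
  fgDiff <- min(object@nucleusColor[3] - object@nucleusColor[2],
                object@plateletColor[3] - object@plateletColor[2])
  if (fgDiff - bgDiff < 30)
    return("nucleus/platelet B-G must exceed background/erythrocyte B-G by >= 30")
  for (cell in object@cells) {
    if (!cell$type %in% c("unilobar", "polylobar"))
      return("cell type must be unilobar or polylobar")
    if (cell$type == "unilobar" && cell$lobeCount != 1L)
      return("unilobar cells must have lobeCount 1")
    if (cell$type == "polylobar" &&
        (cell$lobeCount < 2L || cell$lobeCount > 5L))
      return("polylobar cells must have 2-5 lobes")
    if (cell$type == "polylobar" &&
        !cell$connection %in% c("filament", "overlap", "disconnected"))
      return("connection must be filament, overlap or disconnected")
  }
  if (length(object@cells) >= 2) {
    ext <- vapply(object@cells, cellExtentRadius, numeric(1))
    ctr <- t(vapply(object@cells, function(cl) as.numeric(cl$center),
                    numeric(2)))
    for (i in seq_len(length(object@cells) - 1))
      for (j in seq(i + 1, length(object@cells))) {
        d <- sqrt(sum((ctr[i, ] - ctr[j, ])^2))
        if (d < ext[i] + ext[j])
          return("cells overlap; the scene must be unambiguous")
      }
  }
  TRUE
})

#' Ground truth for a synthetic smear
#'
#' One binary mask per leukocyte (all lobes of a cell share one mask),
#' the cell types, and the platelet mask. Serves as the oracle for
#' segmentation and counting tests.
#'
#' @slot masks list of logical matrices, one per cell; pairwise disjoint.
#' @slot types character vector of cell types (N/E/B/M/L) per mask.
#' @slot lobar character vector, "unilobar"/"polylobar" per mask.
#' @slot plateletMask logical matrix.
#' @slot cellCount integer, equals \code{length(masks)}.
#' @export
setClass("SmearTruth",
         representation(masks = "list", types = "character",
                        lobar = "character", plateletMask = "matrix",
                        cellCount = "integer"))

setValidity("SmearTruth", function(object) {
  if (object@cellCount != length(object@masks))
    return("cellCount must equal number of masks")
  if (length(object@types) != length(object@masks))
    return("one type per mask required")
  if (length(object@masks) >= 2) {
    acc <- Reduce(`+`, lapply(object@masks, function(m) m * 1L))
    if (max(acc) > 1L) return("nucleus masks must be disjoint")
  }
  TRUE
})

#' Full analysis of one smear image
#'
#' Everything [analyzeSmear()] computes for one micrograph: the B-G
#' difference image, the Otsu threshold used, the nucleus label map
#' before and after lobe merging, the shape-feature table, the
#' polylobar/unilobar decisions, and the final [CountReport-class].
#'
#' @slot difference integer matrix, clamped B-G difference image.
#' @slot threshold numeric, gray threshold actually applied.
#' @slot nucleusMap [LabelMap-class] after the platelet area filter,
#'   before merging.
#' @slot features data.frame of shape descriptors per region (pre-merge).
#' @slot mergedMap [LabelMap-class] after minimal-distance lobe merging.
#' @slot decisions data.frame of final per-region decisions
#'   (label, verdict, rule).
#' @slot report the final [CountReport-class].
#' @slot params the [PipelineParams-class] used.
#' @export
setClass("SmearAnalysis",
         representation(difference = "matrix", threshold = "numeric",
                        nucleusMap = "LabelMap", features = "data.frame",
                        mergedMap = "LabelMap", decisions = "data.frame",
                        report = "CountReport", params = "PipelineParams"))
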