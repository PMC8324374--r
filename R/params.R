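#' Parameter constructors
#'
#' Friendly constructors for the S4 parameter classes; arguments default
#' to the class prototypes, which are calibrated for the default
#' synthetic smear geometry.
#'
#' @param otsuOverride,areaThreshold,connectivity see
#'   [SegmentationParams-class].
#' @return the corresponding parameter object.
#' @export
segmentationParams <- function(otsuOverride = NA_real_, areaThreshold = 150,
                               connectivity = 8L) {
  new("SegmentationParams", otsuOverride = as.numeric(otsuOverride),
      areaThreshold = as.numeric(areaThreshold),
      connectivity = as.integer(connectivity))
}

#' @rdname segmentationParams
#' @param x1,x2,x3,x4,x5 see [LobeThresholds-class].
#' @export
lobeThresholds <- function(x1 = 0.90, x2 = 0.78, x3 = 0.55, x4 = 0.80,
                           x5 = 250) {
  new("LobeThresholds", x1 = x1, x2 = x2, x3 = x3, x4 = x4, x5 = x5)
}

#' @rdname segmentationParams
#' @param dMax,dMaxFactor,aMax,maxIterations,cannySigma,cannyLow,cannyHigh
#'   see [MergeParams-class].
#' @export
mergeParams <- function(dMax = NA_real_, dMaxFactor = 0.6, aMax = 2500,
                        maxIterations = 100L, cannySigma = 1.0,
                        cannyLow = 0.1, cannyHigh = 0.3) {
  new("MergeParams", dMax = as.numeric(dMax), dMaxFactor = dMaxFactor,
      aMax = aMax, maxIterations = as.integer(maxIterations),
      cannySigma = cannySigma, cannyLow = cannyLow, cannyHigh = cannyHigh)
}

#' @rdname segmentationParams
#' @param segmentation,thresholds,merge component parameter objects.
#' @export
pipelineParams <- function(segmentation = segmentationParams(),
                           thresholds = lobeThresholds(),
                           merge = mergeParams()) {
  new("PipelineParams", segmentation = segmentation,
      thresholds = thresholds, merge = merge)
}

setMethod("show", "PipelineParams", function(object) {
  s <- object@segmentation; t <- object@thresholds; m <- object@merge
  cat("PipelineParams\n")
  cat(sprintf("  segmentation: S = %g px, connectivity %d, Otsu %s\n",
              s@areaThreshold, s@connectivity,
              if (is.na(s@otsuOverride)) "automatic"
              else sprintf("override %g", s@otsuOverride)))
  cat(sprintf("  cascade: x1 = %g, x2 = %g, x3 = %g, x4 = %g, x5 = %g px\n",
              t@x1, t@x2, t@x3, t@x4, t@x5))
  cat(sprintf("  merge: dMax %s, aMax = %g px, canny sigma %g (%g/%g)\n",
              if (is.na(m@dMax))
                sprintf("%g x equivalent diameter", m@dMaxFactor)
              else sprintf("%g px", m@dMax),
              m@aMax, m@cannySigma, m@cannyLow, m@cannyHigh))
  invisible(NULL)
})

knownConfigKeys <- list(
  segmentation = c("otsu_override", "area_threshold", "connectivity"),
  thresholds = c("x1", "x2", "x3", "x4", "x5"),
  merge = c("d_max", "d_max_factor", "a_max", "max_iterations",
            "canny_sigma", "canny_low", "canny_high"))

#' Read pipeline parameters from a YAML config
#'
#' Parses a YAML file with the sections \code{segmentation} (keys
#' \code{otsu_override}, \code{area_threshold}, \code{connectivity}),
#' \code{thresholds} (\code{x1}..\code{x5}) and \code{merge}
#' (\code{d_max}, \code{d_max_factor}, \code{a_max},
#' \code{max_iterations}, \code{canny_sigma}, \code{canny_low},
#' \code{canny_high}). Missing keys keep their defaults; unknown keys
#' are rejected so typos cannot silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return a [PipelineParams-class].
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  bad <- setdiff(names(cfg), names(knownConfigKeys))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in names(knownConfigKeys)) {
    extra <- setdiff(names(cfg[[sec]]), knownConfigKeys[[sec]])
    if (length(extra))
      stop("unknown key(s) in ", sec, ": ", paste(extra, collapse = ", "))
  }
  g <- function(sec, key, default) {
    v <- cfg[[sec]][[key]]
    if (is.null(v)) default else v
  }
  pipelineParams(
    segmentation = segmentationParams(
      otsuOverride = g("segmentation", "otsu_override", NA_real_),
      areaThreshold = g("segmentation", "area_threshold", 150),
      connectivity = g("segmentation", "connectivity", 8L)),
    thresholds = lobeThresholds(
      x1 = g("thresholds", "x1", 0.90), x2 = g("thresholds", "x2", 0.78),
      x3 = g("thresholds", "x3", 0.55), x4 = g("thresholds", "x4", 0.80),
      x5 = g("thresholds", "x5", 250)),
    merge = mergeParams(
      dMax = g("merge", "d_max", NA_real_),
      dMaxFactor = g("merge", "d_max_factor", 0.6),
      aMax = g("merge", "a_max", 2500),
      maxIterations = g("merge", "max_iterations", 100L),
      cannySigma = g("merge", "canny_sigma", 1.0),
      cannyLow = g("merge", "canny_low", 0.1),
      cannyHigh = g("merge", "canny_high", 0.3)))
}

#' @rdname readPipelineConfig
#' @param params a [PipelineParams-class] to serialize.
#' @export
writePipelineConfig <- function(params, path) {
  stopifnot(is(params, "PipelineParams"))
  s <- params@segmentation; t <- params@thresholds; m <- params@merge
  cfg <- list(
    segmentation = list(
      otsu_override = if (is.na(s@otsuOverride)) NULL else s@otsuOverride,
      area_threshold = s@areaThreshold,
      connectivity = s@connectivity),
    thresholds = list(x1 = t@x1, x2 = t@x2, x3 = t@x3, x4 = t@x4, x5 = t@x5),
    merge = list(
      d_max = if (is.na(m@dMax)) NULL else m@dMax,
      d_max_factor = m@dMaxFactor, a_max = m@aMax,
      max_iterations = m@maxIterations, canny_sigma = m@cannySigma,
      canny_low = m@cannyLow, canny_high = m@cannyHigh))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Calibrate cascade thresholds from labeled features
#'
#' Derives the decision-cascade thresholds from feature tables of
#' regions of known identity, using the same extremum rule that sets the
#' platelet area threshold from the minimum training nucleus area: each
#' threshold is placed at the extreme of the whole-nucleus (unilobar)
#' class, so any region beyond it is flagged as a polylobar candidate.
#' Specifically \code{x1 = max(e)}, \code{x2 = min(P2)},
#' \code{x3 = min(P1)} and \code{x5 = min(A)} over the unilobar table;
#' \code{x4} keeps the supplied posture default, as both classes span
#' the full posture range.
#'
#' @param unilobar feature table ([shapeFeatures()] rows) of whole
#'   single-lobed nuclei.
#' @param x4 aspect-ratio threshold to retain.
#' @return a [LobeThresholds-class].
#' @export
calibrateThresholds <- function(unilobar, x4 = 0.80) {
  need <- c("A", "P1", "P2", "e")
  if (!all(need %in% names(unilobar)) || nrow(unilobar) == 0)
    stop("need a non-empty unilobar feature table with A, P1, P2, e")
  lobeThresholds(x1 = max(unilobar$e), x2 = min(unilobar$P2),
                 x3 = min(unilobar$P1), x4 = x4, x5 = min(unilobar$A))
}
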