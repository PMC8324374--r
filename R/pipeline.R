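#' Analyze one blood-smear micrograph end to end
#'
#' Runs the full counting pipeline on an RGB micrograph: B-G channel
#' difference, Otsu (or overridden) threshold, binarization,
#' connected-component labeling, platelet area filter, shape-feature
#' extraction, the polylobar decision cascade, minimal-distance lobe
#' merging, and the final count.
#'
#' @param img RGB array (see [loadImage()]) or a [SmearSpec-class]
#'   (rendered first).
#' @param params a [PipelineParams-class].
#' @param types optional ground-truth cell types for the per-type
#'   tallies of the report (see [countNuclei()]).
#' @return a [SmearAnalysis-class].
#' @examples
#' res <- analyzeSmear(casePreset(1, seed = 7))
#' totalCount(countReport(res))   # one 3-lobed nucleus counts once
#' @export
analyzeSmear <- function(img, params = pipelineParams(), types = NULL) {
  stopifnot(is(params, "PipelineParams"))
  if (is(img, "SmearSpec")) img <- makeCellImage(img)$image
  assertRgb(img)
  diff <- channelDifference(img)
  s <- params@segmentation
  seg <- thresholdAndLabel(diff, s)
  t1 <- seg$t1
  lmap <- seg$map
  feats <- shapeFeatures(lmap)
  merged <- mergeLobes(lmap, params@thresholds, params@merge,
                       connectivity = s@connectivity)
  report <- countNuclei(merged$map, merged$decisions, types = types)
  new("SmearAnalysis", difference = diff, threshold = as.numeric(t1),
      nucleusMap = lmap, features = feats, mergedMap = merged$map,
      decisions = merged$decisions, report = report, params = params)
}

#' @rdname SmearAnalysis-class
#' @export
setMethod("countReport", "SmearAnalysis", function(x) x@report)

#' @rdname SmearAnalysis-class
#' @export
setMethod("mergedMap", "SmearAnalysis", function(x) x@mergedMap)

#' @rdname SmearAnalysis-class
#' @export
setMethod("nucleusMap", "SmearAnalysis", function(x) x@nucleusMap)

#' @rdname SmearAnalysis-class
#' @export
setMethod("shapeTable", "SmearAnalysis", function(x) x@features)

#' @rdname SmearAnalysis-class
#' @export
setMethod("lobeDecisions", "SmearAnalysis", function(x) x@decisions)

setMethod("show", "SmearAnalysis", function(object) {
  cat(sprintf("SmearAnalysis: %d x %d px, Otsu threshold %g\n",
              nrow(object@difference), ncol(object@difference),
              object@threshold))
  cat(sprintf("  regions: %d before merging, %d after\n",
              nComponents(object@nucleusMap), nComponents(object@mergedMap)))
  show(object@report)
  invisible(NULL)
})

#' Serialize a label map
#'
#' Writes the label matrix as a 16-bit single-channel TIFF plus a JSON
#' sidecar listing every component label and area, and reads the pair
#' back losslessly.
#'
#' @param lmap a [LabelMap-class].
#' @param path output TIFF path; the sidecar gets \code{.json} appended.
#' @export
writeLabelMap <- function(lmap, path) {
  stopifnot(is(lmap, "LabelMap"))
  lab <- labelMatrix(lmap)
  if (max(lab) > 65535) stop("more than 65535 labels cannot be serialized")
  tiff::writeTIFF(lab / 65535, where = path, bits.per.sample = 16L)
  side <- list(n = nComponents(lmap),
               labels = seq_len(nComponents(lmap)),
               areas = componentAreas(lmap))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeLabelMap
#' @export
readLabelMap <- function(path) {
  lab <- tiff::readTIFF(path)
  new("LabelMap", labels = matrix(as.integer(round(lab * 65535)),
                                  nrow = nrow(lab)))
}

#' Serialize a count report as JSON
#'
#' @param report a [CountReport-class].
#' @param path output path; omit for the JSON string.
#' @export
writeCountReport <- function(report, path = NULL) {
  stopifnot(is(report, "CountReport"))
  obj <- list(T = report@total, polylobar = report@polylobar,
              unilobar = report@unilobar,
              T_N = report@perType[["N"]], T_E = report@perType[["E"]],
              T_B = report@perType[["B"]], T_M = report@perType[["M"]],
              T_L = report@perType[["L"]])
  if (is.null(path)) return(jsonlite::toJSON(obj, auto_unbox = TRUE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' Write an evaluation result as CSV
#'
#' One row per class (class, n, correct, accuracy) plus a pooled Total
#' row.
#'
#' @param ev an [EvalResult-class].
#' @param path output CSV path.
#' @export
writeEvalCSV <- function(ev, path) {
  stopifnot(is(ev, "EvalResult"))
  pc <- ev@perClass
  total <- data.frame(class = "Total", n = sum(pc$n),
                      correct = sum(pc$correct), accuracy = ev@overall)
  utils::write.csv(rbind(pc, total), path, row.names = FALSE)
  invisible(path)
}
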