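#' Count leukocytes from a merged label map
#'
#' The total count \code{T} is the number of connected nucleus regions
#' after lobe merging; the polylobar/unilobar tallies come from the
#' final cascade decisions. Per-type counters (neutrophil, eosinophil,
#' basophil, monocyte, lymphocyte) are only populated when ground-truth
#' cell types are supplied -- no five-type classifier is part of the
#' image pipeline. Supplying more typed cells than counted regions is an
#' inconsistency and raises an error rather than truncating silently.
#'
#' @param merged a [LabelMap-class] at a [mergeLobes()] fixpoint.
#' @param decisions decision data.frame covering every region (from
#'   [mergeLobes()]).
#' @param types optional character vector of ground-truth cell types
#'   (values in N, E, B, M, L), one per true cell in the image.
#' @return a [CountReport-class].
#' @export
countNuclei <- function(merged, decisions, types = NULL) {
  stopifnot(is(merged, "LabelMap"))
  n <- nComponents(merged)
  if (nrow(decisions) != n)
    stop("decisions must cover every region of the merged map")
  poly <- sum(decisions$verdict == "polylobar")
  perType <- c(N = 0L, E = 0L, B = 0L, M = 0L, L = 0L)
  if (!is.null(types) && length(types) > 0) {
    if (!all(types %in% names(perType)))
      stop("types must be among N, E, B, M, L")
    if (length(types) > n)
      stop("per-type total exceeds the counted total T; counting stopped")
    tt <- table(factor(types, levels = names(perType)))
    perType <- stats::setNames(as.integer(tt), names(perType))
  }
  new("CountReport", total = as.integer(n), polylobar = as.integer(poly),
      unilobar = as.integer(n - poly), perType = perType)
}

#' @rdname CountReport-class
#' @export
setMethod("totalCount", "CountReport", function(x) x@total)

#' @rdname CountReport-class
#' @export
setMethod("polylobarCount", "CountReport", function(x) x@polylobar)

#' @rdname CountReport-class
#' @export
setMethod("unilobarCount", "CountReport", function(x) x@unilobar)

#' @rdname CountReport-class
#' @export
setMethod("perTypeCounts", "CountReport", function(x) x@perType)

setMethod("show", "CountReport", function(object) {
  cat(sprintf("CountReport: T = %d (%d polylobar, %d unilobar)\n",
              object@total, object@polylobar, object@unilobar))
  if (sum(object@perType) > 0) {
    cat("  per type:",
        paste(sprintf("T_%s = %d", names(object@perType), object@perType),
              collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' Accuracy percentage at printed precision
#'
#' Converts a correct/total pair to a percentage truncated (not rounded)
#' to one decimal place, the convention used when reporting segmentation
#' ratios: 290/300 prints as 96.6, 295/300 as 98.3.
#'
#' @param correct,n counts.
#' @return numeric percentage with one decimal.
#' @export
accuracyPercent <- function(correct, n) {
  ifelse(n > 0, floor(correct / n * 1000) / 10, NA_real_)
}

#' Build an evaluation result from per-class tallies
#'
#' Assembles an [EvalResult-class] from already-known per-class sample
#' and correct counts. The pooled accuracy is always
#' \code{sum(correct) / sum(n)}, never the mean of the class accuracies.
#'
#' @param class character vector of class names.
#' @param n,correct integer vectors of samples and correctly counted
#'   images per class.
#' @return an [EvalResult-class].
#' @export
evalResult <- function(class, n, correct) {
  stopifnot(length(class) == length(n), length(n) == length(correct),
            all(correct <= n))
  perClass <- data.frame(class = as.character(class), n = as.integer(n),
                         correct = as.integer(correct),
                         accuracy = accuracyPercent(correct, n),
                         stringsAsFactors = FALSE)
  new("EvalResult", perClass = perClass,
      overall = accuracyPercent(sum(correct), sum(n)))
}

# TRUE iff the predicted regions of `merged` match the ground-truth
# nucleus masks one-to-one by majority pixel overlap.
regionsMatchTruth <- function(merged, truth) {
  n <- nComponents(merged)
  if (n != truth@cellCount) return(FALSE)
  if (n == 0) return(TRUE)
  assigned <- integer(n)
  for (k in seq_len(n)) {
    px <- componentPixels(merged, k)
    hits <- vapply(truth@masks, function(m)
      sum(m[cbind(px[, "y"], px[, "x"])]), numeric(1))
    if (max(hits) <= nrow(px) / 2) return(FALSE)   # majority overlap required
    assigned[k] <- which.max(hits)
  }
  length(unique(assigned)) == n
}

#' Evaluate counting accuracy against ground truth
#'
#' For each image, the prediction is correct when the predicted
#' leukocyte count equals the ground-truth cell count and the predicted
#' regions map one-to-one onto the ground-truth nucleus masks by
#' majority pixel overlap -- the strictest testable reading of a
#' per-image segmentation ratio. Results are aggregated per class and
#' pooled.
#'
#' @param predictions list of [SmearAnalysis-class] objects (or lists
#'   with a \code{map} [LabelMap-class] element).
#' @param truths list of [SmearTruth-class] objects, same length.
#' @param classes optional character vector of per-image class labels
#'   (defaults to each image's first ground-truth cell type).
#' @return an [EvalResult-class].
#' @export
evaluateSegmentation <- function(predictions, truths, classes = NULL) {
  if (length(predictions) != length(truths))
    stop("predictions and truths must have equal length")
  if (length(predictions) == 0) stop("nothing to evaluate")
  maps <- lapply(predictions, function(p) {
    if (is(p, "SmearAnalysis")) mergedMap(p)
    else if (is.list(p) && !is.null(p$map)) p$map
    else stop("predictions must be SmearAnalysis objects or lists with $map")
  })
  if (is.null(classes)) {
    classes <- vapply(truths, function(tr)
      if (length(tr@types)) tr@types[1] else "unknown", character(1))
  }
  ok <- mapply(regionsMatchTruth, maps, truths)
  cls <- sort(unique(classes))
  n <- vapply(cls, function(cl) sum(classes == cl), integer(1))
  correct <- vapply(cls, function(cl) sum(ok[classes == cl]), integer(1))
  evalResult(cls, n, correct)
}

#' @rdname EvalResult-class
#' @export
setMethod("overallAccuracy", "EvalResult", function(x) x@overall)

#' @rdname EvalResult-class
#' @export
setMethod("perClassAccuracy", "EvalResult", function(x) x@perClass)

setMethod("show", "EvalResult", function(object) {
  cat("EvalResult (count-correct images per class):\n")
  print(object@perClass, row.names = FALSE)
  cat(sprintf("  pooled accuracy: %.1f%% (%d/%d)\n", object@overall,
              sum(object@perClass$correct), sum(object@perClass$n)))
  invisible(NULL)
})
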