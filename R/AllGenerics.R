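#' @rdname LabelMap-class
#' @param x a \code{LabelMap} (or object containing one).
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname LabelMap-class
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname LabelMap-class
#' @export
setGeneric("componentAreas", function(x) standardGeneric("componentAreas"))

#' @rdname LabelMap-class
#' @param label a component label in \code{1..nComponents(x)}.
#' @export
setGeneric("componentPixels",
           function(x, label) standardGeneric("componentPixels"))

#' @rdname LabelMap-class
#' @export
setGeneric("componentMask",
           function(x, label) standardGeneric("componentMask"))

#' @rdname CountReport-class
#' @param x a \code{CountReport} (or object containing one).
#' @export
setGeneric("totalCount", function(x) standardGeneric("totalCount"))

#' @rdname CountReport-class
#' @export
setGeneric("polylobarCount", function(x) standardGeneric("polylobarCount"))

#' @rdname CountReport-class
#' @export
setGeneric("unilobarCount", function(x) standardGeneric("unilobarCount"))

#' @rdname CountReport-class
#' @export
setGeneric("perTypeCounts", function(x) standardGeneric("perTypeCounts"))

#' @rdname EvalResult-class
#' @param x an \code{EvalResult}.
#' @export
setGeneric("overallAccuracy", function(x) standardGeneric("overallAccuracy"))

#' @rdname EvalResult-class
#' @export
setGeneric("perClassAccuracy", function(x) standardGeneric("perClassAccuracy"))

#' @rdname SmearAnalysis-class
#' @param x a \code{SmearAnalysis}.
#' @export
setGeneric("countReport", function(x) standardGeneric("countReport"))

#' @rdname SmearAnalysis-class
#' @export
setGeneric("mergedMap", function(x) standardGeneric("mergedMap"))

#' @rdname SmearAnalysis-class
#' @export
setGeneric("nucleusMap", function(x) standardGeneric("nucleusMap"))

#' @rdname SmearAnalysis-class
#' @export
setGeneric("shapeTable", function(x) standardGeneric("shapeTable"))

#' @rdname SmearAnalysis-class
#' @export
setGeneric("lobeDecisions", function(x) standardGeneric("lobeDecisions"))
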