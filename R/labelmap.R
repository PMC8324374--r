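#' @describeIn LabelMap-class construct a \code{LabelMap} from a labeled
#'   integer matrix (relabeled compactly in row-major first-encounter
#'   order if needed).
#' @param labels an integer matrix of non-negative labels.
#' @export
LabelMap <- function(labels) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  labels <- relabelRowMajor(labels)
  new("LabelMap", labels = labels)
}

# Compact labels to 1..n in row-major first-encounter order. Row-major
# means scanning rows top to bottom, columns left to right within a row.
relabelRowMajor <- function(labels) {
  pos <- which(labels > 0)
  if (length(pos) == 0) return(labels)
  nr <- nrow(labels)
  r <- (pos - 1L) %% nr
  cc <- (pos - 1L) %/% nr
  ord <- order(r, cc)
  first <- labels[pos][ord][!duplicated(labels[pos][ord])]
  out <- labels
  out[pos] <- match(labels[pos], first)
  storage.mode(out) <- "integer"
  out
}

#' @rdname LabelMap-class
#' @export
setMethod("labelMatrix", "LabelMap", function(x) x@labels)

#' @rdname LabelMap-class
#' @export
setMethod("nComponents", "LabelMap", function(x) {
  if (length(x@labels) == 0) 0L else max(x@labels)
})

#' @rdname LabelMap-class
#' @export
setMethod("componentAreas", "LabelMap", function(x) {
  n <- nComponents(x)
  if (n == 0L) return(integer(0))
  tabulate(x@labels[x@labels > 0L], nbins = n)
})

#' @describeIn LabelMap-class pixel coordinates of one component as a
#'   two-column matrix with columns \code{x} (column index) and \code{y}
#'   (row index), 1-based.
#' @export
setMethod("componentPixels", "LabelMap", function(x, label) {
  stopifnot(length(label) == 1, label >= 1, label <= nComponents(x))
  idx <- which(x@labels == label)
  nr <- nrow(x@labels)
  cbind(x = (idx - 1L) %/% nr + 1L, y = (idx - 1L) %% nr + 1L)
})

#' @describeIn LabelMap-class logical mask of one component.
#' @export
setMethod("componentMask", "LabelMap", function(x, label) {
  stopifnot(length(label) == 1, label >= 1, label <= nComponents(x))
  x@labels == label
})

setMethod("show", "LabelMap", function(object) {
  n <- nComponents(object)
  cat(sprintf("LabelMap: %d x %d pixels, %d component%s\n",
              nrow(object@labels), ncol(object@labels), n,
              if (n == 1) "" else "s"))
  if (n > 0) {
    a <- componentAreas(object)
    cat(sprintf("  areas: min %d, median %.0f, max %d px\n",
                min(a), stats::median(a), max(a)))
  }
  invisible(NULL)
})

# Coordinates (x = col, y = row) of every foreground pixel of a logical
# or 0/1 matrix.
maskPixels <- function(mask) {
  idx <- which(mask > 0)
  nr <- nrow(mask)
  cbind(x = (idx - 1L) %/% nr + 1L, y = (idx - 1L) %% nr + 1L)
}
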