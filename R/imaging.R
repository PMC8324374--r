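## Raster image handling. RGB images are integer arrays H x W x 3 with
## channel values in [0, 255] (channels in R, G, B order, origin at the
## top-left, first index = row). Gray images are integer matrices in
## [0, 255]; binary masks are logical or 0/1 matrices.

assertRgb <- function(img) {
  if (!(is.array(img) && length(dim(img)) == 3 && dim(img)[3] == 3))
    stop("expected an RGB image: an H x W x 3 array")
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop("RGB channel values must be in [0, 255]")
  invisible(img)
}

assertGray <- function(gray) {
  if (!is.matrix(gray)) stop("expected a gray image: an H x W matrix")
  if (anyNA(gray) || min(gray) < 0 || max(gray) > 255)
    stop("gray values must be in [0, 255]")
  invisible(gray)
}

assertMask <- function(mask) {
  if (!is.matrix(mask)) stop("expected a binary mask matrix")
  v <- unique(as.vector(mask * 1L))
  if (!all(v %in% c(0L, 1L))) stop("mask values must be 0/1")
  invisible(mask)
}

#' Read an 8-bit RGB micrograph
#'
#' Reads a PNG, TIFF or uncompressed 24-bit BMP image into an integer
#' \code{H x W x 3} array with channels in (R, G, B) order and values in
#' \[0, 255\], regardless of on-disk layout. Sixteen-bit, palette,
#' grayscale and alpha-carrying images are rejected rather than silently
#' converted, so the pipeline always sees the pixel values the
#' microscope camera wrote.
#'
#' @param path path to an image file; the extension selects the decoder.
#' @return integer array \code{H x W x 3}.
#' @examples
#' tmp <- tempfile(fileext = ".png")
#' img <- array(c(10L, 20L, 200L), dim = c(1, 1, 3))
#' saveImage(img, tmp)
#' stopifnot(identical(loadImage(tmp), img))
#' @export
loadImage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    info <- attr(raw, "info")
    if (!is.null(info) && !is.null(info$bit.depth) && info$bit.depth != 8)
      stop("unsupported format: only 8-bit-per-channel PNG is accepted")
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(raw, "bits.per.sample")
    if (!is.null(bits) && any(bits != 8))
      stop("unsupported format: only 8-bit-per-channel TIFF is accepted")
  } else if (ext == "bmp") {
    return(readBmp24(path))
  } else {
    stop("unsupported format: ", ext, " (PNG, TIFF or BMP expected)")
  }
  if (length(dim(raw)) != 3 || dim(raw)[3] != 3)
    stop("unsupported format: an 8-bit RGB image without alpha is required")
  img <- array(as.integer(round(raw * 255)), dim = dim(raw))
  assertRgb(img)
}

# Minimal decoder for uncompressed 24-bit bottom-up BMP (BI_RGB).
readBmp24 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  if (!identical(rawToChar(magic), "BM")) stop("unsupported format: not a BMP")
  invisible(readBin(con, "integer", 2, size = 4))        # file size, reserved
  offset <- readBin(con, "integer", 1, size = 4)
  hdrSize <- readBin(con, "integer", 1, size = 4)
  if (hdrSize < 40) stop("unsupported format: BMP header too old")
  w <- readBin(con, "integer", 1, size = 4)
  h <- readBin(con, "integer", 1, size = 4)
  invisible(readBin(con, "integer", 1, size = 2))        # planes
  bits <- readBin(con, "integer", 1, size = 2)
  comp <- readBin(con, "integer", 1, size = 4)
  if (bits != 24 || comp != 0)
    stop("unsupported format: only uncompressed 24-bit BMP is accepted")
  seek(con, offset)
  rowBytes <- ((w * 3 + 3) %/% 4) * 4
  bytes <- readBin(con, "raw", rowBytes * abs(h))
  img <- array(0L, dim = c(abs(h), w, 3))
  for (row in seq_len(abs(h))) {
    line <- as.integer(bytes[((row - 1) * rowBytes + 1):((row - 1) * rowBytes + w * 3)])
    y <- if (h > 0) abs(h) - row + 1 else row    # positive h = bottom-up
    img[y, , 1] <- line[seq(3, w * 3, 3)]        # BGR on disk
    img[y, , 2] <- line[seq(2, w * 3, 3)]
    img[y, , 3] <- line[seq(1, w * 3, 3)]
  }
  assertRgb(img)
}

#' Write an image losslessly
#'
#' Writes an RGB image, gray image or binary mask to PNG or TIFF
#' (selected by the file extension). Masks are stored as 0/255
#' single-channel images; [loadImage()]/[png::readPNG()] round-trips are
#' bit exact.
#'
#' @param img RGB array, gray matrix or binary mask.
#' @param path output path ending in .png, .tif or .tiff.
#' @export
saveImage <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  if (is.matrix(img)) {
    if (is.logical(img) || all(img %in% c(0, 1))) {
      dat <- (img > 0) * 1.0            # mask -> 0/255 gray
    } else {
      assertGray(img)
      dat <- img / 255
    }
  } else {
    assertRgb(img)
    dat <- img / 255
  }
  ok <- switch(ext,
               png = { png::writePNG(dat, target = path); TRUE },
               tif = , tiff = { tiff::writeTIFF(dat, where = path); TRUE },
               stop("unsupported output format: ", ext))
  invisible(ok)
}

#' Blue-minus-green channel difference
#'
#' Computes the per-pixel difference \code{clamp(B - G, 0, 255)}. After
#' Wright's staining, nuclei are blue-purple and platelets stain
#' similarly, so their blue channel exceeds their green channel by a
#' large margin, while the light background and the pink erythrocytes
#' have nearly equal B and G. The difference image therefore carries
#' nuclei and platelets as the bright classes, which is what makes a
#' single global Otsu threshold sufficient. The red channel is ignored
#' entirely.
#'
#' @param img RGB array (see [loadImage()]).
#' @return integer matrix in \[0, 255\].
#' @export
channelDifference <- function(img) {
  assertRgb(img)
  d <- img[, , 3, drop = TRUE] - img[, , 2, drop = TRUE]
  d[d < 0] <- 0L
  storage.mode(d) <- "integer"
  if (!is.matrix(d)) d <- matrix(d, nrow = dim(img)[1])
  d
}

#' Gray-level histogram
#'
#' Counts pixels at each of the 256 gray levels. The sum of the counts
#' always equals the pixel count of the image.
#'
#' @param gray integer matrix in \[0, 255\].
#' @return integer vector of length 256, named "0".."255".
#' @export
grayHistogram <- function(gray) {
  assertGray(gray)
  counts <- tabulate(as.vector(gray) + 1L, nbins = 256L)
  names(counts) <- 0:255
  counts
}

#' Stain a mask onto an image
#'
#' Diagnostic overlay: pixels where the mask is set are replaced by the
#' stain color, every other pixel is returned bit-identically. Overlaying
#' the segmented nucleus mask on the original micrograph makes over- and
#' under-segmentation visible at the nucleus rim.
#'
#' @param img RGB array.
#' @param mask binary mask of the same height/width.
#' @param color RGB triple in \[0, 255\]; default a saturated red.
#' @return RGB array.
#' @export
renderOverlay <- function(img, mask, color = c(255L, 0L, 0L)) {
  assertRgb(img)
  assertMask(mask)
  if (!all(dim(mask) == dim(img)[1:2]))
    stop("mask dimensions must equal image dimensions")
  stopifnot(length(color) == 3, all(color >= 0), all(color <= 255))
  out <- img
  sel <- mask > 0
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[sel] <- as.integer(color[ch])
    out[, , ch] <- plane
  }
  out
}
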