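test_that("channel difference is B minus G, clamped, and ignores R", {
  img <- array(0L, dim = c(2, 2, 3))
  img[1, 1, ] <- c(100L, 50L, 200L)   # B - G = 150
  img[1, 2, ] <- c(100L, 200L, 50L)   # clamps to 0
  img[2, 1, ] <- c(77L, 77L, 77L)     # gray: B = G
  img[2, 2, ] <- c(0L, 10L, 255L)
  d <- channelDifference(img)
  expect_identical(d[1, 1], 150L)
  expect_identical(d[1, 2], 0L)
  expect_identical(d[2, 1], 0L)
  expect_identical(d[2, 2], 245L)

  set.seed(42)
  rnd <- array(sample(0:255, 5 * 4 * 3, TRUE), dim = c(5, 4, 3))
  perturbed <- rnd
  perturbed[, , 1] <- sample(0:255, 20, TRUE)
  expect_identical(channelDifference(rnd), channelDifference(perturbed))
})

test_that("histogram counts every pixel exactly once", {
  g <- matrix(7L, 2, 2)
  h <- grayHistogram(g)
  expect_identical(unname(h[8]), 4L)
  expect_identical(sum(h), 4L)

  g2 <- matrix(c(0L, 0L, 255L, 3L), 2, 2)
  h2 <- grayHistogram(g2)
  expect_identical(unname(h2[c(1, 4, 256)]), c(2L, 1L, 1L))

  set.seed(1)
  for (i in 1:5) {
    g3 <- matrix(sample(0:255, 30 * 17, TRUE), 30, 17)
    expect_identical(sum(grayHistogram(g3)), 30L * 17L)
  }
})

test_that("overlay stains exactly the mask and preserves the rest", {
  set.seed(7)
  img <- array(sample(0:255, 6 * 6 * 3, TRUE), dim = c(6, 6, 3))
  zero <- matrix(0L, 6, 6)
  expect_identical(renderOverlay(img, zero), img)

  ones <- matrix(1L, 6, 6)
  red <- renderOverlay(img, ones, c(255L, 0L, 0L))
  expect_true(all(red[, , 1] == 255L) && all(red[, , 2] == 0L))

  single <- zero; single[3, 4] <- 1L
  out <- renderOverlay(img, single, c(1L, 2L, 3L))
  changed <- which(out != img)
  expect_identical(out[3, 4, ], c(1L, 2L, 3L))
  expect_lte(length(changed), 3)
  expect_error(renderOverlay(img, matrix(0L, 5, 6)), "dimensions")
})

test_that("save/load round-trips PNG and TIFF bit-exactly", {
  set.seed(11)
  img <- array(sample(0:255, 8 * 9 * 3, TRUE), dim = c(8, 9, 3))
  for (ext in c(".png", ".tif")) {
    f <- tempfile(fileext = ext)
    saveImage(img, f)
    expect_identical(loadImage(f), img)
  }
  one <- array(255L, dim = c(1, 1, 3))
  f1 <- tempfile(fileext = ".png")
  saveImage(one, f1)
  expect_identical(loadImage(f1), one)
})

test_that("masks round-trip through 0/255 grayscale PNG", {
  set.seed(3)
  mask <- randomMask(10, 12)
  f <- tempfile(fileext = ".png")
  saveImage(mask, f)
  back <- png::readPNG(f)
  expect_identical((back > 0.5) * 1L, unname(mask))
})

test_that("unsupported inputs are rejected explicitly", {
  expect_error(loadImage(tempfile(fileext = ".png")), "not found")

  f <- tempfile(fileext = ".png")       # RGBA must be refused, not coerced
  png::writePNG(array(0.5, dim = c(4, 4, 4)), f)
  expect_error(loadImage(f), "unsupported")

  g <- tempfile(fileext = ".png")       # grayscale likewise
  png::writePNG(matrix(0.5, 4, 4), g)
  expect_error(loadImage(g), "unsupported")

  txt <- tempfile(fileext = ".xyz")
  writeLines("hi", txt)
  expect_error(loadImage(txt), "unsupported")
})

test_that("24-bit BMP files load with channels in RGB order", {
  # hand-written 2x2 BMP: bottom-up rows, BGR samples, 2-byte row padding
  f <- tempfile(fileext = ".bmp")
  con <- file(f, "wb")
  writeBin(charToRaw("BM"), con)
  writeBin(c(70L, 0L), con, size = 4)           # file size, reserved
  writeBin(54L, con, size = 4)                  # pixel offset
  writeBin(c(40L, 2L, 2L), con, size = 4)       # header size, w, h
  writeBin(1L, con, size = 2); writeBin(24L, con, size = 2)
  writeBin(c(0L, 16L, 0L, 0L, 0L, 0L), con, size = 4)
  # bottom row: (R=1,G=2,B=3), (R=4,G=5,B=6); top row: (7,8,9), (10,11,12)
  writeBin(as.raw(c(3, 2, 1, 6, 5, 4, 0, 0)), con)
  writeBin(as.raw(c(9, 8, 7, 12, 11, 10, 0, 0)), con)
  close(con)
  img <- loadImage(f)
  expect_identical(img[2, 1, ], c(1L, 2L, 3L))  # bottom-left
  expect_identical(img[1, 2, ], c(10L, 11L, 12L))
})
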