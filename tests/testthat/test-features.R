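test_that("area and bounding rectangle follow the pixel set", {
  rect <- matrix(0L, 10, 10); rect[2:5, 3:5] <- 1L  # 4 rows x 3 cols
  expect_identical(componentArea(rect), 12L)
  r <- boundingRectangle(rect)
  expect_identical(r$a1, 3L)    # horizontal extent
  expect_identical(r$b1, 4L)    # vertical extent

  two <- cbind(x = c(2L, 5L), y = c(3L, 3L))
  r2 <- boundingRectangle(two)
  expect_identical(c(r2$a1, r2$b1), c(4L, 1L))

  single <- cbind(x = 4L, y = 9L)
  expect_identical(componentArea(single), 1L)
  r1 <- boundingRectangle(single)
  expect_identical(c(r1$a1, r1$b1), c(1L, 1L))
})

test_that("rectangle plumpness and aspect ratio are exact on rectangles", {
  rect <- matrix(0L, 20, 20); rect[4:7, 2:11] <- 1L  # 10 wide x 4 tall
  expect_identical(rectPlumpness(rect), 1.0)
  expect_identical(aspectRatio(rect), 0.4)
  expect_identical(aspectRatio(list(a1 = 4, b1 = 10)), 2.5)

  diagonal <- cbind(x = 1:5, y = 1:5)
  expect_identical(rectPlumpness(diagonal), 0.2)
  expect_identical(aspectRatio(diagonal), 1.0)

  sq <- matrix(1L, 6, 6)
  expect_identical(aspectRatio(sq), 1.0)
})

test_that("disk and ellipse calibration of the moment descriptors", {
  disk <- rasterDisk(20)
  f <- featureVector(disk)
  # bounding box is 2r+1 wide, so P1 sits (2r/(2r+1))^2 below pi/4;
  # the bias shrinks as r grows (see the r = 40 calibration elsewhere)
  expect_lt(abs(f$P1 - pi / 4), 0.05)
  expect_equal(f$a2, 20, tolerance = 0.03 * 20)
  expect_equal(f$b2, 20, tolerance = 0.03 * 20)
  expect_lt(f$e, 0.1)
  expect_equal(f$P2, 1.0, tolerance = 0.03)

  ell <- rasterEllipse(30, 10)
  fe <- featureVector(ell)
  expect_equal(fe$a2, 30, tolerance = 0.03 * 30)
  expect_equal(fe$b2, 10, tolerance = 0.03 * 10)
  expect_equal(fe$P2, 1.0, tolerance = 0.03)
  el <- fitEllipse(ell)
  expect_lt(abs(el$orientation), 0.05)
})

test_that("moment ellipse agrees with EBImage's moments on a disk", {
  skip_if_not_installed("EBImage")
  disk <- rasterDisk(15)
  ft <- EBImage::computeFeatures.moment(EBImage::bwlabel(disk))
  el <- fitEllipse(disk)
  expect_equal(2 * el$a2, unname(ft[1, "m.majoraxis"]), tolerance = 0.02)
  expect_equal(eccentricity(el), unname(ft[1, "m.eccentricity"]),
               tolerance = 0.05)
})

test_that("eccentricity follows its closed form", {
  expect_identical(eccentricity(list(a2 = 5, b2 = 3)), 0.8)
  expect_identical(eccentricity(list(a2 = 4, b2 = 4)), 0.0)
  expect_gt(eccentricity(list(a2 = 1, b2 = 1e-6)), 0.999)
  expect_error(eccentricity(list(a2 = 3, b2 = 5)), "b2 > a2")
})

test_that("P2 drops far below 1 for two distant disks seen as one region", {
  d1 <- rasterDisk(8, pad = 2)
  big <- matrix(FALSE, 40, 120)
  big[10 + seq_len(nrow(d1)), 5 + seq_len(ncol(d1))] <- d1
  big[10 + seq_len(nrow(d1)), 90 + seq_len(ncol(d1))] <- d1
  p2 <- ellipsePlumpness(big)
  expect_lt(p2, 0.5)
  expect_equal(ellipsePlumpness(rasterDisk(12)), 1.0, tolerance = 0.03)
})

test_that("feature vector equals per-formula recomputation on random blobs", {
  set.seed(99)
  for (i in 1:10) {
    m <- randomMask(20, 25, 0.5)
    if (!any(m > 0)) next
    px <- which(m > 0, arr.ind = TRUE)
    coords <- cbind(x = px[, 2], y = px[, 1])
    f <- featureVector(coords)
    A <- nrow(coords)
    a1 <- diff(range(coords[, "x"])) + 1
    b1 <- diff(range(coords[, "y"])) + 1
    expect_identical(f$A, A)
    expect_equal(f$P1, A / (a1 * b1))
    expect_equal(f$s, b1 / a1)
    expect_equal(f$e, sqrt(f$a2^2 - f$b2^2) / f$a2)
    if (!f$degenerate) expect_equal(f$P2, A / (pi * f$a2 * f$b2))
  }
})

test_that("features are translation invariant; 90-degree rotation flips s", {
  set.seed(55)
  m <- matrix(0L, 30, 30)
  m[5:12, 4:20] <- 1L; m[10:18, 8:12] <- 1L
  px <- componentPixels(labelComponents(m), 1)
  f0 <- featureVector(px)
  shifted <- cbind(x = px[, "x"] + 7L, y = px[, "y"] + 3L)
  expect_equal(featureVector(shifted), f0)

  rotated <- cbind(x = px[, "y"], y = max(px[, "x"]) + 1L - px[, "x"])
  fr <- featureVector(rotated)
  expect_identical(fr$A, f0$A)
  expect_equal(fr$P1, f0$P1)
  expect_equal(fr$P2, f0$P2)
  expect_equal(fr$e, f0$e)
  expect_equal(fr$s, 1 / f0$s)
})

test_that("degenerate components are floored and flagged", {
  f1 <- featureVector(cbind(x = 3L, y = 3L))
  expect_true(f1$degenerate)
  expect_identical(f1$b2, 0.5)
  line <- cbind(x = 1:6, y = rep(2L, 6))
  fl <- featureVector(line)
  expect_true(fl$degenerate)
  expect_warning(ellipsePlumpness(cbind(x = 1L, y = 1L)), "degenerate")
})
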