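test_that("Otsu picks the smallest maximizer of between-class variance", {
  h <- integer(256)
  h[51] <- 100; h[201] <- 100        # equal mass at levels 50 and 200
  expect_identical(otsuThreshold(h), 50L)

  flat <- integer(256); flat[101] <- 37
  expect_identical(otsuThreshold(flat), 0L)  # single class: no split helps
  zero <- integer(256); zero[1] <- 10
  expect_identical(otsuThreshold(zero), 0L)

  expect_error(otsuThreshold(integer(256)), "empty")
})

test_that("Otsu agrees with the exhaustive oracle on random histograms", {
  set.seed(101)
  for (i in 1:100) {
    h <- randomHistogram()
    expect_identical(otsuThreshold(h), as.integer(bruteOtsu(h)))
  }
})

test_that("binarize uses a strict greater-than at the threshold", {
  u <- matrix(10L, 3, 3)
  expect_true(all(binarize(u, 10) == 0L))
  g <- matrix(c(0L, 255L, 0L, 255L), 2, 2)
  expect_identical(binarize(g, 0), (g > 0) * 1L)
  expect_true(all(binarize(matrix(255L, 2, 2), 255) == 0L))
})

test_that("labeling respects connectivity and matches flood-fill", {
  diagPair <- matrix(0L, 3, 3)
  diagPair[1, 1] <- 1L; diagPair[2, 2] <- 1L
  expect_identical(nComponents(labelComponents(diagPair, 8)), 1L)
  expect_identical(nComponents(labelComponents(diagPair, 4)), 2L)
  expect_identical(nComponents(labelComponents(matrix(0L, 4, 4))), 0L)

  set.seed(202)
  for (i in 1:20) {
    m <- randomMask(15, 15, p = runif(1, 0.2, 0.6))
    conn <- sample(c(4, 8), 1)
    expect_identical(nComponents(labelComponents(m, conn)),
                     as.integer(floodCount(m, conn)))
  }
})

test_that("labeling matches EBImage on 4-connectivity", {
  skip_if_not_installed("EBImage")
  set.seed(42)
  for (i in 1:5) {
    m <- randomMask(20, 20, 0.4)
    expect_identical(nComponents(labelComponents(m, 4)),
                     as.integer(max(EBImage::bwlabel(m))))
  }
})

test_that("labels are assigned in row-major first-encounter order", {
  m <- matrix(0L, 4, 6)
  m[3, 1] <- 1L      # encountered later (row 3)
  m[1, 5] <- 1L      # first foreground pixel in a row-major scan
  m[2, 2] <- 1L
  lm <- labelComponents(m, 4)
  expect_identical(labelMatrix(lm)[1, 5], 1L)
  expect_identical(labelMatrix(lm)[2, 2], 2L)
  expect_identical(labelMatrix(lm)[3, 1], 3L)
})

test_that("area filter keeps exactly the components with area >= S", {
  m <- matrix(0L, 40, 40)
  m[1:1, 1:5] <- 1L                  # area 5
  m[10:14, 1:8] <- 1L                # area 40
  m[20:39, 1:20] <- 1L               # area 400
  lm <- labelComponents(m, 8)
  kept <- areaFilter(lm, 50)
  expect_identical(nComponents(kept), 1L)
  expect_identical(componentAreas(kept), 400L)

  expect_identical(labelMatrix(areaFilter(lm, 0)), labelMatrix(lm))
  expect_identical(nComponents(areaFilter(lm, 401)), 0L)
})

test_that("area filter matches a per-component oracle and is idempotent", {
  set.seed(303)
  for (i in 1:20) {
    lm <- labelComponents(randomMask(25, 25, runif(1, 0.3, 0.6)), 8)
    S <- sample(1:30, 1)
    filtered <- areaFilter(lm, S)
    expect_identical(sort(componentAreas(filtered)),
                     sort(componentAreas(lm)[componentAreas(lm) >= S]))
    expect_identical(labelMatrix(areaFilter(filtered, S)),
                     labelMatrix(filtered))
    # monotonicity: larger S never keeps more
    expect_lte(nComponents(areaFilter(lm, S + 5)), nComponents(filtered))
  }
})

test_that("area-threshold calibration takes the minimum training area", {
  expect_identical(calibrateAreaThreshold(c(400, 900, 1200)), 400)
  expect_identical(calibrateAreaThreshold(77), 77)
  expect_equal(calibrateAreaThreshold(c(400, 900), factor = 0.9), 360)
  expect_error(calibrateAreaThreshold(numeric(0)), "at least one")
})

test_that("segmentNuclei keeps nuclei, drops platelets, and is deterministic", {
  spec <- smearSpec(cells = list(list(
    type = "unilobar", lobeCount = 1L, lobeRadius = 16, gap = 0,
    connection = "none", axisRatio = 1.1, angle = 0.3,
    center = c(128, 128), cellType = "L")), plateletCount = 6L, seed = 5L)
  sc <- makeCellImage(spec)
  lm <- segmentNuclei(sc$image)
  expect_identical(nComponents(lm), 1L)
  expect_gt(componentAreas(lm), 600)

  blank <- makeCellImage(smearSpec(cells = list(), plateletCount = 0L,
                                   erythrocyteCount = 0L, seed = 1L))
  expect_identical(nComponents(segmentNuclei(blank$image)), 0L)

  lm2 <- segmentNuclei(sc$image)
  expect_identical(labelMatrix(lm), labelMatrix(lm2))
})
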