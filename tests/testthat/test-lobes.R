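test_that("decision cascade fires its rules in order", {
  th <- lobeThresholds(x1 = 0.90, x2 = 0.60, x3 = 0.55, x4 = 0.80, x5 = 250)
  feat <- function(e, P2, P1 = 0.9, s = 1, A = 900)
    data.frame(A = A, P1 = P1, s = s, P2 = P2, e = e, degenerate = FALSE)

  d1 <- classifyComponents(feat(e = 0.95, P2 = 0.40), th)
  expect_identical(d1$verdict, "polylobar")
  expect_identical(d1$rule, "rule2_ecc")

  d2 <- classifyComponents(feat(e = 0.10, P2 = 0.95), th)
  expect_identical(d2$verdict, "unilobar")
  expect_identical(d2$rule, "none")

  d3 <- classifyComponents(feat(e = 0.10, P2 = 0.95, A = 100), th)
  expect_identical(d3$rule, "rule4_area")

  d4 <- classifyComponents(feat(e = 0.10, P2 = 0.95, P1 = 0.40, s = 0.5), th)
  expect_identical(d4$rule, "rule3_rect")

  dg <- data.frame(A = 1, P1 = 1, s = 1, P2 = NA_real_, e = 0,
                   degenerate = TRUE)
  expect_warning(dd <- classifyComponents(dg, th), "degenerate")
  expect_identical(dd$verdict, "unilobar")
})

test_that("edges of simple shapes look like their boundaries", {
  disk <- rasterDisk(10)
  e <- detectEdges(disk)
  expect_gt(nrow(e), 2 * pi * 10 * 0.8)
  expect_lt(nrow(e), 2 * pi * 10 * 1.2)
  # every edge pixel sits within 2 px of the analytic circle
  ctr <- (nrow(disk) + 1) / 2
  rad <- sqrt((e[, "x"] - ctr)^2 + (e[, "y"] - ctr)^2)
  expect_true(all(abs(rad - 10) < 2.5))

  rect <- matrix(0L, 30, 30); rect[10:20, 5:25] <- 1L
  er <- detectEdges(rect)
  expect_true(all(er[, "x"] >= 4 & er[, "x"] <= 26))
  inner <- er[, "x"] > 6 & er[, "x"] < 24 & er[, "y"] > 12 & er[, "y"] < 18
  expect_false(any(inner))  # no edges deep inside the rectangle

  single <- matrix(0L, 5, 5); single[3, 2] <- 1L
  expect_identical(detectEdges(single), cbind(x = 2L, y = 3L))
})

test_that("minimal pair distance matches brute force and breaks ties stably", {
  r <- minPairDistance(cbind(x = 0L, y = 0L), cbind(x = 3L, y = 4L))
  expect_identical(r$d, 5)
  same <- cbind(x = c(1L, 2L), y = c(1L, 2L))
  expect_identical(minPairDistance(same, same)$d, 0)

  set.seed(77)
  for (i in 1:100) {
    ea <- cbind(x = sample(1:50, 8, TRUE), y = sample(1:50, 8, TRUE))
    eb <- cbind(x = sample(1:50, 6, TRUE), y = sample(1:50, 6, TRUE))
    expect_equal(minPairDistance(ea, eb)$d, bruteMinDist(ea, eb))
  }
  expect_error(minPairDistance(cbind(x = 1, y = 1)[0, , drop = FALSE],
                               cbind(x = 1, y = 1)), "non-empty")
})

test_that("connecting a pair draws the digital line and fills rings", {
  m <- matrix(0L, 8, 8)
  m[1, 1] <- 1L; m[6, 1] <- 1L
  out <- connectPair(m, c(1, 1), c(1, 6))
  expect_identical(sum(out), 6L)
  expect_identical(nComponents(labelComponents(out)), 1L)

  expect_identical(connectPair(m, c(1, 1), c(1, 1)), m)

  # a ring (annulus) is filled solid once touched
  ring <- rasterDisk(9) & !rasterDisk(5, pad = 7)   # both 25 x 25, centered
  filled <- connectPair(ring * 1L, c(13, 4), c(13, 4))
  expect_identical(sum(filled), sum(rasterDisk(9)))

  expect_error(connectPair(m, c(0, 1), c(2, 2)), "out of")
})

test_that("hole filling agrees with EBImage::fillHull", {
  skip_if_not_installed("EBImage")
  ring <- (rasterDisk(9) & !rasterDisk(5, pad = 7)) * 1L
  ours <- connectPair(ring, c(13, 4), c(13, 4))
  theirs <- EBImage::fillHull(ring)
  expect_identical(ours, matrix(as.integer(theirs), nrow(theirs)))
})

test_that("three disconnected lobes merge into one region", {
  sc <- makeCellImage(casePreset(1, seed = 9))
  lm <- segmentNuclei(sc$image)
  expect_identical(nComponents(lm), 3L)
  res <- mergeLobes(lm)
  expect_identical(nComponents(res$map), 1L)
  expect_identical(res$nMerges, 2L)
})

test_that("nearby unilobar nuclei are never merged or absorbed", {
  sc <- makeCellImage(casePreset(2, seed = 4))
  lm <- segmentNuclei(sc$image)
  res <- mergeLobes(lm)
  expect_identical(nComponents(res$map), 2L)
  expect_identical(res$nMerges, 0L)
  # unilobar regions are bit-identical before and after
  expect_identical(labelMatrix(res$map), labelMatrix(lm))

  sc3 <- makeCellImage(casePreset(3, seed = 4))
  lm3 <- segmentNuclei(sc3$image)
  res3 <- mergeLobes(lm3)
  expect_identical(nComponents(res3$map), 2L)
  uni <- sc3$truth@masks[[which(sc3$truth@lobar == "unilobar")]]
  after <- labelMatrix(res3$map)
  lab <- unique(after[uni])
  lab <- lab[lab > 0]
  expect_identical(length(lab), 1L)
  expect_identical(sum(after == lab), sum(segmentNuclei(sc3$image)@labels > 0 & uni))
})

test_that("merging is idempotent at its fixpoint and respects the caps", {
  for (seed in c(2, 13)) {
    sc <- makeCellImage(casePreset(4, seed = seed))
    lm <- segmentNuclei(sc$image)
    res <- mergeLobes(lm)
    expect_identical(nComponents(res$map), 2L)
    expect_lte(nComponents(res$map), nComponents(lm))
    again <- mergeLobes(res$map)
    expect_identical(labelMatrix(again$map), labelMatrix(res$map))
    expect_identical(again$nMerges, 0L)
  }
})

test_that("no merge bridges a gap beyond the distance cap", {
  # two small candidate regions far apart must both survive
  m <- matrix(0L, 60, 60)
  d <- rasterDisk(7, pad = 0)
  m[3 + seq_len(nrow(d)), 3 + seq_len(ncol(d))] <- d
  m[40 + seq_len(nrow(d)), 40 + seq_len(ncol(d))] <- d
  lm <- labelComponents(m)
  expect_identical(nComponents(lm), 2L)
  res <- mergeLobes(lm)   # gap ~ 32 px >> 0.6 x equivalent diameter
  expect_identical(nComponents(res$map), 2L)
})
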