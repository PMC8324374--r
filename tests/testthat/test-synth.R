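test_that("rendering is deterministic and empty specs give blank scenes", {
  spec <- casePreset(1, seed = 42)
  a <- makeCellImage(spec)
  b <- makeCellImage(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth@masks, b$truth@masks)

  blank <- makeCellImage(smearSpec(cells = list(), plateletCount = 0L,
                                   erythrocyteCount = 0L, seed = 1L))
  expect_identical(blank$truth@cellCount, 0L)
  expect_identical(length(unique(as.vector(blank$image[, , 3]))), 1L)
})

test_that("disconnected lobes appear as separate regions in the truth mask", {
  spec <- casePreset(1, seed = 8)   # single 3-lobed disconnected nucleus
  sc <- makeCellImage(spec)
  expect_identical(sc$truth@cellCount, 1L)
  mask <- sc$truth@masks[[1]]
  expect_identical(nComponents(labelComponents(mask * 1L, 8)), 3L)
})

test_that("connection modes control the component structure of a cell", {
  base <- list(type = "polylobar", lobeCount = 3L, lobeRadius = 8,
               angle = 0.4, center = c(128, 128), cellType = "N")
  for (mode in c("filament", "overlap", "disconnected")) {
    cell <- base
    cell$connection <- mode
    cell$gap <- switch(mode, filament = 3, overlap = -4, disconnected = 6.5)
    sc <- makeCellImage(smearSpec(cells = list(cell), seed = 3L,
                                  plateletCount = 0L, erythrocyteCount = 0L))
    n <- nComponents(labelComponents(sc$truth@masks[[1]] * 1L, 8))
    expect_identical(n, if (mode == "disconnected") 3L else 1L)
  }
})

test_that("generated scenes keep the B-G classes separable by >= 30 levels", {
  for (seed in 1:6) {
    sc <- makeCellImage(casePreset(sample(1:4, 1), seed = seed))
    d <- channelDifference(sc$image)
    fg <- Reduce(`|`, sc$truth@masks) | sc$truth@plateletMask
    expect_gte(min(d[fg]) - max(d[!fg]), 30)
  }
})

test_that("platelet areas sit below S and lobe areas at or above it", {
  S <- 150
  ds <- makeDataset(12, seed = 31)
  for (sc in ds) {
    pl <- sc$truth@plateletMask
    if (any(pl)) {
      areas <- componentAreas(labelComponents(pl * 1L, 8))
      expect_true(all(areas < S))
    }
    for (m in sc$truth@masks) {
      lobes <- componentAreas(labelComponents(m * 1L, 8))
      expect_true(all(lobes >= S))
    }
  }
})

test_that("datasets are reproducible and share leading substreams", {
  d1 <- makeDataset(5, seed = 9)
  d2 <- makeDataset(5, seed = 9)
  expect_identical(d1[[3]]$image, d2[[3]]$image)
  d3 <- makeDataset(6, seed = 9)
  for (i in 1:5) expect_identical(d3[[i]]$image, d1[[i]]$image)

  counts <- table(vapply(makeDataset(30, seed = 2),
                         function(sc) sc$truth@types[1], character(1)))
  expect_identical(sum(counts), 30L)
  expect_error(makeDataset(5, mix = c(a = 1)), "named")
})

test_that("case presets realize their scenarios", {
  s1 <- casePreset(1, seed = 3)
  expect_identical(length(s1@cells), 1L)
  expect_identical(s1@cells[[1]]$connection, "disconnected")
  expect_gte(s1@cells[[1]]$lobeCount, 2L)

  s2 <- casePreset(2, seed = 3)
  expect_identical(vapply(s2@cells, `[[`, character(1), "type"),
                   c("unilobar", "unilobar"))

  s4 <- casePreset(4, seed = 3)
  expect_identical(vapply(s4@cells, `[[`, character(1), "type"),
                   c("polylobar", "polylobar"))
  expect_error(casePreset(5), "1, 2, 3 or 4")
})

test_that("overlapping cells in a spec are rejected", {
  cell <- list(type = "unilobar", lobeCount = 1L, lobeRadius = 16, gap = 0,
               connection = "none", axisRatio = 1.1, angle = 0,
               center = c(100, 100), cellType = "L")
  cell2 <- cell
  cell2$center <- c(110, 100)
  expect_error(smearSpec(cells = list(cell, cell2)), "overlap")
})
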