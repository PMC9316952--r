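# Sliding inference, heatmap rendering round-trips, and detection merging.

test_that("inference grids have lattice dimensions and batch invariance", {
  model <- buildModel(tinyBcnnConfig())
  g <- generateTile(tinySynth(tileWidth = 128L, tileHeight = 128L,
                              nCells = 2L))
  grid <- slidingInference(model, g$tile)
  expect_equal(dim(scores(grid)), c(7L, 7L))
  expect_true(all(scores(grid) >= 0 & scores(grid) <= 1))
  grid1 <- slidingInference(model, g$tile, batchSize = 7L)
  expect_equal(scores(grid), scores(grid1), tolerance = 1e-6)
})

test_that("a trained model keeps pure background below threshold", {
  model <- tinyTrainedModel()
  bg <- generateTile(syntheticConfig(tileWidth = 256L, tileHeight = 256L,
                                     nCells = 0L, nNegatives = 0L,
                                     nucleiDensity = 60L, seed = 77L))
  grid <- slidingInference(model, bg$tile)
  expect_lt(max(scores(grid)), 0.5)
})

test_that("rendering paints stride blocks and is invertible", {
  m <- matrix(0, 5, 6)
  grid <- gridFromMatrix(m)
  img <- renderHeatmap(grid)
  expect_equal(dim(img), c(50, 60, 3))
  pal <- heatmapPalette()
  expect_true(all(img[, , 1] == pal$negative[1]))

  m[2, 3] <- 0.9
  grid <- gridFromMatrix(m)
  img <- renderHeatmap(grid)
  red <- img[, , 1] == 1 & img[, , 2] == 0 & img[, , 3] == 0
  expect_equal(sum(red), 100)
  expect_true(all(red[11:20, 21:30]))
  expect_identical(maskFromRendered(img, 10L), m >= 0.5)

  expect_error(renderHeatmap(grid, palette = list(positive = c(1, 0, 0),
                                                  negative = c(1, 0, 0))),
               "distinct")
})

test_that("detection merging resolves isolated and neighbouring cells", {
  m <- matrix(0, 10, 10)
  m[4, 5] <- 0.8
  det <- mergeDetections(gridFromMatrix(m))
  expect_equal(nrow(det), 1L)
  expect_equal(det$x, 32L + 4L * 10L)
  expect_equal(det$y, 32L + 3L * 10L)
  detC <- mergeDetections(gridFromMatrix(m), method = "components")
  expect_equal(detC[, c("x", "y")], det[, c("x", "y")])

  # two supra cells separated by a sub-threshold lattice cell
  m2 <- matrix(0, 10, 10)
  m2[4, 3] <- 0.9; m2[4, 4] <- 0.2; m2[4, 5] <- 0.8
  expect_equal(nrow(mergeDetections(gridFromMatrix(m2),
                                    method = "components")), 2L)
  m3 <- matrix(0, 10, 10)
  m3[4, 3] <- 0.9; m3[4, 6] <- 0.8    # 30 px apart, beyond suppression
  expect_equal(nrow(mergeDetections(gridFromMatrix(m3))), 2L)

  expect_equal(nrow(mergeDetections(gridFromMatrix(matrix(0, 5, 5)))), 0L)
})

test_that("peak detection count is monotone non-increasing in the threshold", {
  # (the component rule is not monotone: a component splits in two when its
  # bridge cell drops below the threshold, so only the default rule is held
  # to the invariant)
  set.seed(4)
  for (i in 1:100) {
    m <- matrix(runif(400), 20, 20)
    grid <- gridFromMatrix(m)
    counts <- vapply(seq(0.1, 0.9, by = 0.1), function(th)
      nrow(mergeDetections(grid, th)), 1)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("detections carry case-frame coordinates from the tile origin", {
  m <- matrix(0, 10, 10); m[2, 2] <- 1
  grid <- new("HeatmapGrid", scores = m, stride = 10L, originOffset = 32L,
              caseId = "c", tileId = "t", tileOrigin = c(512, 256),
              micronsPerPixel = 0.25)
  det <- mergeDetections(grid)
  expect_equal(det$case_x, det$x + 512L)
  expect_equal(det$case_y, det$y + 256L)
})
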