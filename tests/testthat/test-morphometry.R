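# Cell segmentation and measurement: binarization, contour tracing, area /
# perimeter / compactness, and case-level summaries.

test_that("binarization thresholds strictly and is idempotent", {
  sig <- matrix(seq(0, 1, length.out = 100), 10, 10)
  expect_false(any(binarizeSignal(sig, 1)))
  m <- binarizeSignal(sig, 0.5)
  for (s2 in c(0.2, 0.5, 0.8))
    expect_identical(binarizeSignal(m * 1, s2), m)
  expect_error(binarizeSignal(sig, 1.5), "sigma")
})

test_that("contours of rectangles simplify to their four corners", {
  mask <- matrix(FALSE, 20, 30)
  mask[5:12, 8:21] <- TRUE
  ct <- extractCellContour(mask)
  sim <- simplifyContour(ct)
  expect_equal(nrow(sim), 4L)
  expect_setequal(paste(sim[, 1], sim[, 2]),
                  c("7 4", "20 4", "20 11", "7 11"))
  m <- measureCell(mask)
  expect_equal(m$area, 8 * 14)
  expect_equal(m$perimeter, 2 * 7 + 2 * 13)
})

test_that("the largest component is selected; degenerate masks fail", {
  mask <- matrix(FALSE, 40, 40)
  mask[2:26, 2:21] <- TRUE            # 500 px
  mask[30:36, 30:36] <- TRUE          # 49 px
  ct <- extractCellContour(mask)
  expect_true(all(ct[, 1] <= 20 & ct[, 2] <= 25))

  expect_error(extractCellContour(matrix(FALSE, 5, 5)), "no segmentable")
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_error(extractCellContour(single), "no segmentable")
})

test_that("compactness approaches closed forms for squares and discs", {
  sq <- matrix(FALSE, 220, 220)
  sq[10:209, 10:209] <- TRUE
  m <- measureCell(sq)
  expect_equal(m$area, 200^2)
  expect_lt(abs(m$compactness - 4 / pi), 0.02 * 4 / pi)

  d60 <- measureCell(discMask(60))
  expect_gte(d60$compactness, 0.95)
  expect_lte(d60$compactness, 1.15)

  # scale behaviour: drift below 5% between radii 30 and 120
  d30 <- measureCell(discMask(30))
  d120 <- measureCell(discMask(120))
  expect_lt(abs(d30$compactness - d120$compactness) / d120$compactness, 0.05)
})

test_that("contour-enclosed area equals the pixel count on random blobs", {
  set.seed(6)
  for (i in 1:50) {
    mask <- randomBlobMask()
    m <- measureCell(mask)
    expect_equal(m$area, sum(mask))
    expect_gte(m$compactness, 0.9)   # blobs of overlapping discs stay round
  }
})

test_that("ring annuli enclose their lumen and record sigma", {
  mask <- discMask(12) & !discMask(7, pad = 9L)  # annulus, same centre
  m <- measureCell(mask, sigma = 0.42)
  expect_equal(m$min_intensity, 0.42)
  expect_gte(m$area, sum(discMask(12)) - 80)     # lumen counted
  expect_gte(m$compactness, 0.9)
})

test_that("binarized generator rings match the rendered ring pixel count", {
  cfg <- syntheticConfig(tileWidth = 128L, tileHeight = 128L, nCells = 1L,
                         nNegatives = 0L, nucleiDensity = 0L,
                         cellRadiusRange = c(12, 12), haloRingWidth = 4,
                         stainIntensityRange = c(0.8, 0.8),
                         backgroundNoiseSd = 0.01, seed = 19L)
  g <- generateTile(cfg)
  p <- g$marks[1, ]
  crop <- tileArray(g$tile)[(p$y - 31):(p$y + 32), (p$x - 31):(p$x + 32), ]
  sig <- preprocessPatch(crop, gaussianSigma = 0.5, enhance = FALSE)
  s <- otsuStatistic(sig)
  fg <- sum(binarizeSignal(sig, s))
  ringPx <- sum(discMask(12) & !discMask(8, pad = 8L))
  expect_lt(abs(fg - ringPx) / ringPx, 0.1)
})

test_that("case summaries are means plus a density", {
  cells <- data.frame(area_px = c(100, 200), perimeter_px = c(40, 60),
                      compactness = c(1.1, 1.3), min_intensity = c(0.2, 0.4))
  cs <- caseSummary(cells, tissueAreaMm2 = 0.5)
  expect_equal(cs$mean_area_px, 150)
  expect_equal(cs$density_per_mm2, 4)
  expect_equal(caseSummary(cells[2:1, ], 0.5), cs, ignore_attr = TRUE)

  one <- caseSummary(cells[1, ], 1)
  expect_equal(one$mean_compactness, 1.1)
  expect_equal(caseSummary(cells, 10)$density_per_mm2, 0.2)

  empty <- caseSummary(cells[0, ], 1)
  expect_equal(empty$n_cells, 0L)
  expect_equal(empty$density_per_mm2, 0)
  expect_true(is.na(empty$mean_area_px))
  expect_error(caseSummary(cells, 0), "positive")
})
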