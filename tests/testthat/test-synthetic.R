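# Synthetic stained-tissue generator: determinism, ground-truth fidelity,
# geometric constraints and per-region density control.

test_that("identical configuration and seed give bit-identical output", {
  cfg <- tinySynth()
  a <- generateTile(cfg)
  b <- generateTile(cfg)
  expect_identical(tileArray(a$tile), tileArray(b$tile))
  expect_identical(a$marks, b$marks)
})

test_that("nCells = 0 yields a tile without positive marks", {
  g <- generateTile(tinySynth(nCells = 0L))
  expect_equal(sum(g$marks$label == "positive"), 0L)
  expect_equal(sum(g$marks$label == "negative"), 4L)
})

test_that("recorded stain intensity can be read back from the raster", {
  cfg <- syntheticConfig(tileWidth = 512L, tileHeight = 512L, nCells = 20L,
                         nNegatives = 0L, nucleiDensity = 0L,
                         cellRadiusRange = c(10, 10), haloRingWidth = 4,
                         stainIntensityRange = c(0.6, 0.9), seed = 31L)
  g <- generateTile(cfg)
  pos <- g$marks[g$marks$label == "positive", ]
  expect_true(all(pos$intensity >= 0.6 & pos$intensity <= 0.9))
  arr <- tileArray(g$tile)
  lum <- 0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3]
  for (i in seq_len(nrow(pos))) {
    ys <- (pos$y[i] - 12):(pos$y[i] + 12) + 1L
    xs <- (pos$x[i] - 12):(pos$x[i] + 12) + 1L
    d <- sqrt(outer((ys - 1 - pos$y[i])^2, (xs - 1 - pos$x[i])^2, `+`))
    ring <- d >= 6.5 & d <= 9.5   # interior of the rendered annulus [6, 10]
    stain <- mean(1 - lum[ys, xs][ring])
    expect_lt(abs(stain - pos$intensity[i]), 0.05)
  }
})

test_that("positive centres respect borders and pairwise separation", {
  cfg <- syntheticConfig(nCells = 80L, seed = 13L)
  g <- generateTile(cfg)
  pos <- g$marks[g$marks$label == "positive", ]
  expect_true(all(pos$x >= 32 & pos$x <= cfg@tileWidth - 32))
  expect_true(all(pos$y >= 32 & pos$y <= cfg@tileHeight - 32))
  d <- as.matrix(dist(pos[, c("x", "y")]))
  diag(d) <- Inf
  expect_gte(min(d), 2 * max(cfg@cellRadiusRange))
  neg <- g$marks[g$marks$label == "negative", ]
  dneg <- sqrt(outer(neg$x, pos$x, `-`)^2 + outer(neg$y, pos$y, `-`)^2)
  expect_gte(min(dneg), 64)
})

test_that("infeasible packing fails naming the constraint", {
  expect_error(generateTile(tinySynth(nCells = 200L)),
               "infeasible packing")
})

test_that("a case is additive over tiles and shares one case id", {
  cfg <- tinySynth(tileWidth = 256L, tileHeight = 256L, nCells = 10L,
                   nNegatives = 2L)
  cs <- generateCase(cfg, nTiles = 4, caseId = "caseX")
  expect_length(cs$tiles, 4L)
  expect_equal(sum(cs$marks$label == "positive"), 40L)
  expect_setequal(unique(cs$marks$case_id), "caseX")
  expect_error(generateCase(cfg, nTiles = 0), "at least 1")
  # case-frame coordinates include the tile origin
  t2 <- cs$tiles[[2]]
  m2 <- cs$marks[cs$marks$tile_id == tileId(t2), ]
  expect_equal(m2$case_x, m2$x + t2@origin[1])
})

test_that("a single-class feature raster assigns every cell that class", {
  cfg <- tinySynth(nCells = 6L)
  fm <- featureMapSpec(320, 160, classes = "viable_tumour",
                       palette = matrix(c(0.9, 0.7, 0.1), 1))
  cs <- generateCase(cfg, featureMap = fm, nTiles = 2, caseId = "c")
  pos <- cs$marks[cs$marks$label == "positive", ]
  expect_setequal(featureClassAt(fm, pos$case_x, pos$case_y), "viable_tumour")
})

test_that("per-class density weights steer placement (3:1 within 3 sigma)", {
  cfg <- syntheticConfig(nCells = 40L, nNegatives = 0L, nucleiDensity = 40L,
                         seed = 17L)
  fm <- featureMapSpec(512 * 3, 512 * 2, classes = c("a", "b"),
                       palette = rbind(c(1, 0, 0), c(0, 1, 0)))
  cs <- generateCase(cfg, featureMap = fm, nTiles = 6, caseId = "c",
                     classDensity = c(a = 3, b = 1))
  pos <- cs$marks[cs$marks$label == "positive", ]
  cls <- featureClassAt(fm, pos$case_x, pos$case_y)
  n <- length(cls)
  expect_gte(n, 200L)
  pA <- mean(cls == "a")
  expect_lt(abs(pA - 0.75), 3 * sqrt(0.75 * 0.25 / n))
})

test_that("feature map rendering and class lookup are consistent", {
  fm <- featureMapSpec(120, 60, scale = 10)
  img <- renderFeatureMap(fm)
  expect_equal(dim(img), c(60, 120, 3))
  # pixel colour at a probe point equals the palette row of its class
  cls <- featureClassAt(fm, 5, 5)
  k <- match(cls, fm@classes)
  expect_equal(as.numeric(img[6, 6, ]), as.numeric(fm@palette[k, ]))
  expect_equal(featureClassAt(fm, -5, 5), "unassigned")
})
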