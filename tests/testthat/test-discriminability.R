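# Signal preprocessing, the Otsu statistic, the acceptance threshold
# T = mean(sigma) - min(sigma) and the discriminable partition.

test_that("preprocessing handles constant, identity and ring inputs", {
  flat <- array(0.5, dim = c(20, 20, 3))
  sig <- preprocessPatch(flat, gaussianSigma = 1, enhance = FALSE)
  expect_equal(max(sig) - min(sig), 0)
  expect_equal(max(preprocessPatch(flat, 1, TRUE)), 0)  # zero local contrast

  m <- matrix(runif(400), 20, 20)
  expect_equal(preprocessPatch(m, gaussianSigma = 0, enhance = FALSE), 1 - m)

  cfg <- syntheticConfig(tileWidth = 128L, tileHeight = 128L, nCells = 1L,
                         nNegatives = 0L, nucleiDensity = 0L,
                         cellRadiusRange = c(10, 10),
                         stainIntensityRange = c(0.8, 0.8), seed = 3L)
  g <- generateTile(cfg)
  p <- g$marks[1, ]
  crop <- tileArray(g$tile)[(p$y - 31):(p$y + 32), (p$x - 31):(p$x + 32), ]
  sig <- preprocessPatch(crop, gaussianSigma = 0.5, enhance = FALSE)
  d <- sqrt(outer((1:64 - 33)^2, (1:64 - 33)^2, `+`))
  expect_gt(mean(sig[d >= 7 & d <= 9]), mean(sig[d > 20]))
})

test_that("the Otsu statistic equals exhaustive between-class-variance search", {
  set.seed(11)
  for (i in 1:50) {
    kind <- i %% 3
    v <- switch(as.character(kind),
                "0" = runif(500),
                "1" = c(rnorm(300, 0.3, 0.05), rnorm(200, 0.7, 0.05)),
                "2" = sample(c(0.1, 0.4, 0.9), 400, replace = TRUE))
    v <- pmin(pmax(v, 0), 1)
    expect_identical(otsuStatistic(v), bruteOtsu(v))
  }
})

test_that("a noisy symmetric bimodal signal splits near the midpoint", {
  set.seed(12)
  v <- pmin(pmax(c(rnorm(2000, 0.3, 0.05), rnorm(2000, 0.7, 0.05)), 0), 1)
  s <- otsuStatistic(v)
  expect_gt(s, 0.4)
  expect_lt(s, 0.6)
  expect_error(otsuStatistic(rep(0.4, 100)), "constant")
})

test_that("the acceptance threshold is mean minus minimum", {
  sm <- acceptanceThreshold(c(0.010, 0.030, 0.050))
  expect_equal(acceptanceT(sm), 0.020)
  expect_equal(sm@tMin, 0.010)
  expect_equal(sm@n, 3L)
  expect_equal(acceptanceT(acceptanceThreshold(rep(0.4, 7))), 0)
  expect_error(acceptanceThreshold(numeric(0)), "at least one")

  set.seed(13)
  for (i in 1:200) {
    s <- runif(sample(1:50, 1))
    sm <- acceptanceThreshold(s)
    expect_equal(acceptanceT(sm), mean(s) - min(s), tolerance = 1e-14)
    # permutation invariance and affine equivariance of T
    expect_equal(acceptanceT(acceptanceThreshold(rev(s))), acceptanceT(sm))
    expect_equal(acceptanceT(acceptanceThreshold(0.5 * s + 0.1)),
                 0.5 * acceptanceT(sm), tolerance = 1e-12)
  }
})

test_that("the partition is strict, complete and NA-safe", {
  rec <- data.frame(id = 1:3, sigma = c(0.010, 0.030, 0.050))
  sm <- acceptanceThreshold(rec$sigma)
  pa <- partitionDetections(rec, sm)
  expect_equal(pa$discriminable$sigma, c(0.030, 0.050))
  expect_equal(pa$lessDiscriminable$sigma, 0.010)
  expect_equal(nrow(pa$discriminable) + nrow(pa$lessDiscriminable), 3L)

  recEq <- data.frame(sigma = rep(0.3, 5))
  paEq <- partitionDetections(recEq, acceptanceThreshold(recEq$sigma))
  expect_equal(nrow(paEq$discriminable), 5L)

  recNA <- data.frame(sigma = c(0.4, NA))
  paNA <- partitionDetections(recNA, acceptanceThreshold(0.4))
  expect_equal(nrow(paNA$discriminable), 1L)

  # the minimum-sigma record is discriminable iff 2 * tmin > mean(sigma)
  set.seed(14)
  for (i in 1:50) {
    s <- runif(sample(2:30, 1))
    sm <- acceptanceThreshold(s)
    pa <- partitionDetections(data.frame(sigma = s), sm)
    expect_equal(min(s) %in% pa$discriminable$sigma, 2 * min(s) > mean(s))
  }
})

test_that("constant crops yield NA sigma and are less-discriminable", {
  arr <- array(0.5, dim = c(128, 128, 3))
  arr[40:60, 40:60, 1] <- 0.9  # give the case one usable detection
  arr[40:60, 40:60, 3] <- 0.1
  tile <- imageTile(arr, caseId = "c", tileId = "t")
  det <- data.frame(case_id = "c", tile_id = "t", x = c(96, 50),
                    y = c(96, 50), score = 0.9, n_windows = 1L,
                    case_x = c(96, 50), case_y = c(96, 50))
  fl <- filterDetections(list(tile), det)
  expect_true(is.na(fl$detections$sigma[1]))
  expect_false(fl$detections$discriminable[1])
  expect_equal(nrow(fl$detections), 2L)

  # zero detections (e.g. an all-negative slide) pass through unharmed
  fl0 <- filterDetections(list(tile), det[0, ])
  expect_equal(nrow(fl0$detections), 0L)
  expect_length(fl0$summaries, 0L)
})
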