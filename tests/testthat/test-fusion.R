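# Haar wavelet decomposition/fusion, control-point registration, warping
# and cell-heatmap thresholding.

randImg <- function(H, W) array(runif(H * W * 3), dim = c(H, W, 3))
rmsDiff <- function(a, b) sqrt(mean((a - b)^2))

test_that("single-level Haar decomposition reconstructs exactly", {
  set.seed(21)
  for (d in list(c(32, 32), c(31, 33), c(20, 17))) {
    x <- matrix(runif(prod(d)), d[1], d[2])
    expect_lt(rmsDiff(idwt2(dwt2(x)), x), 1e-8)
  }
  expect_error(dwt2(matrix(1, 4, 4), wavelet = "sym4"), "unsupported")
})

test_that("coefficient-averaged fusion equals pixel averaging", {
  set.seed(22)
  X <- randImg(40, 40)
  expect_lt(rmsDiff(dwtFuse(X, X), X), 1e-6)
  black <- X * 0
  expect_lt(rmsDiff(dwtFuse(X, black), X / 2), 1e-6)
  for (i in 1:5) {
    A <- randImg(37, 41); B <- randImg(37, 41)
    expect_lt(rmsDiff(dwtFuse(A, B), clip01((A + B) / 2)), 1e-6)
    expect_identical(dwtFuse(A, B), dwtFuse(B, A))
  }
  expect_error(dwtFuse(randImg(10, 10), randImg(10, 12)), "identical")
})

test_that("affine transforms are recovered from control points", {
  pts <- cbind(c(0, 100, 0, 100, 37), c(0, 0, 80, 80, 55))
  M <- estimateTransform(pts, pts)
  expect_equal(unclass(M), diag(3), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(attr(M, "rmse"), 0, tolerance = 1e-12)

  M2 <- estimateTransform(pts, cbind(pts[, 1] + 10, pts[, 2] - 5))
  expect_equal(M2[1:2, 3], c(10, -5), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(M2[1:2, 1:2], diag(2), tolerance = 1e-9, ignore_attr = TRUE)

  set.seed(23)
  A <- matrix(c(1.05, 0.08, -0.1, 0.97), 2, 2)
  tv <- c(12, -7)
  mov <- cbind(runif(20, 0, 200), runif(20, 0, 200))
  fix <- t(A %*% t(mov) + tv) + matrix(rnorm(40, 0, 0.5), 20, 2)
  M3 <- estimateTransform(mov, fix)
  expect_lt(max(abs(M3[1:2, 1:2] - A)), 0.02)
  expect_lt(max(abs(M3[1:2, 3] - tv)), 1.5)

  expect_error(estimateTransform(pts[1:2, ], pts[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5))
  expect_error(estimateTransform(line, line), "collinear")

  # similarity: rotation + isotropic scale + translation, recovered exactly
  th <- 0.3; s <- 1.4
  R <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  fixS <- t(R %*% t(mov)) + matrix(c(3, -2), 20, 2, byrow = TRUE)
  M4 <- estimateTransform(mov, fixS, type = "similarity")
  expect_equal(M4[1:2, 1:2], R, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("warping with the identity and translations moves pixels exactly", {
  img <- randImg(12, 15)
  expect_equal(warpImage(img, diag(3)), img)
  M <- diag(3); M[1, 3] <- 3; M[2, 3] <- 2
  w <- warpImage(img, M)
  expect_equal(w[3:12, 4:15, ], img[1:10, 1:12, ])
  expect_true(all(w[1:2, , ] == 0))
})

test_that("thresholding keeps only positive-palette pixels", {
  pal <- heatmapPalette()
  m <- matrix(0, 6, 6); m[2, 2] <- 1; m[5, 4] <- 1
  img <- renderHeatmap(gridFromMatrix(m, 5L), palette = pal)
  thr <- thresholdCellHeatmap(img, pal)
  redBlocks <- thr[, , 1] == 1 & thr[, , 2] == 0
  expect_equal(sum(redBlocks), 2 * 25)
  expect_true(all(thr[, , 1][!redBlocks] == 0))
  allNeg <- renderHeatmap(gridFromMatrix(matrix(0, 4, 4), 5L), palette = pal)
  expect_true(all(thresholdCellHeatmap(allNeg, pal) == 0))
  expect_error(thresholdCellHeatmap(img, list(negative = c(0, 0, 1))),
               "positive colour")
  # nonzero pixels equal the upsampled binary lattice
  up <- maskFromRendered(img, 5L, pal)
  expect_identical(up, m >= 0.5)
})

test_that("case fusion composes thresholding, registration and averaging", {
  he <- randImg(60, 60)
  blackCells <- array(0, dim = c(60, 60, 3))
  blackCells[, , 1] <- heatmapPalette()$negative[1]  # not the positive colour
  fz <- fuseCase(he, blackCells, controlPoints = NULL)
  expect_lt(rmsDiff(fz$fused, he / 2), 1e-6)

  m <- matrix(0, 6, 6); m[3, 4] <- 1
  cellMap <- renderHeatmap(gridFromMatrix(m, 10L), palette = heatmapPalette())
  he2 <- array(0.2, dim = c(60, 60, 3))
  cp <- data.frame(moving_x = c(0, 59, 0, 59), moving_y = c(0, 0, 59, 59),
                   fixed_x = c(0, 59, 0, 59), fixed_y = c(0, 0, 59, 59))
  fz2 <- fuseCase(he2, cellMap, cp)
  red <- fz2$fused[, , 1] - fz2$fused[, , 3]
  block <- red > 0.3
  expect_equal(sum(block), 100)             # one 10x10 block survived
  expect_true(all(block[21:30, 31:40]))     # at the lattice offset
})
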