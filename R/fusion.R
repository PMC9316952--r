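# Bimodal heatmap fusion: control-point affine registration, cell-heatmap
# thresholding, and single-level Haar wavelet fusion by coefficient
# averaging per RGB channel.

#' Single-level 2-D Haar wavelet decomposition of a matrix
#'
#' Orthonormal Haar analysis into approximation, horizontal, vertical and
#' diagonal coefficient bands. Odd dimensions are extended by replicating the
#' last row/column; the original size is recorded so [idwt2()] can crop back,
#' and reconstruction of unmodified bands is exact to machine precision.
#'
#' @param x numeric matrix.
#' @param wavelet wavelet family; only `"haar"` (= `"db1"`) is provided.
#' @return list with bands `a`, `h`, `v`, `d`, the family, and `origDim`.
#' @export
dwt2 <- function(x, wavelet = "haar") {
  if (!wavelet %in% c("haar", "db1"))
    stop("unsupported wavelet family: ", wavelet)
  d0 <- dim(x)
  if (d0[1] %% 2L == 1L) x <- rbind(x, x[d0[1], ])
  if (d0[2] %% 2L == 1L) x <- cbind(x, x[, ncol(x)])
  oi <- seq(1L, nrow(x), 2L); ei <- oi + 1L
  lo <- (x[oi, , drop = FALSE] + x[ei, , drop = FALSE]) / sqrt(2)
  hi <- (x[oi, , drop = FALSE] - x[ei, , drop = FALSE]) / sqrt(2)
  oj <- seq(1L, ncol(x), 2L); ej <- oj + 1L
  list(a = (lo[, oj, drop = FALSE] + lo[, ej, drop = FALSE]) / sqrt(2),
       h = (lo[, oj, drop = FALSE] - lo[, ej, drop = FALSE]) / sqrt(2),
       v = (hi[, oj, drop = FALSE] + hi[, ej, drop = FALSE]) / sqrt(2),
       d = (hi[, oj, drop = FALSE] - hi[, ej, drop = FALSE]) / sqrt(2),
       wavelet = "haar", origDim = d0)
}

#' @rdname dwt2
#' @param bands a band list from [dwt2()].
#' @export
idwt2 <- function(bands) {
  lo <- matrix(0, nrow(bands$a), 2L * ncol(bands$a))
  hi <- lo
  oj <- seq(1L, ncol(lo), 2L); ej <- oj + 1L
  lo[, oj] <- (bands$a + bands$h) / sqrt(2)
  lo[, ej] <- (bands$a - bands$h) / sqrt(2)
  hi[, oj] <- (bands$v + bands$d) / sqrt(2)
  hi[, ej] <- (bands$v - bands$d) / sqrt(2)
  x <- matrix(0, 2L * nrow(lo), ncol(lo))
  oi <- seq(1L, nrow(x), 2L); ei <- oi + 1L
  x[oi, ] <- (lo + hi) / sqrt(2)
  x[ei, ] <- (lo - hi) / sqrt(2)
  x[seq_len(bands$origDim[1]), seq_len(bands$origDim[2]), drop = FALSE]
}

#' Fuse two registered RGB images by wavelet coefficient averaging
#'
#' Per channel: single-level discrete wavelet decomposition of both inputs,
#' element-wise averaging of each of the four coefficient bands
#' (`Fused(x, y) = (Img1(x, y) + Img2(x, y)) / 2` in the coefficient
#' domain), inverse transform, channel re-concatenation and clipping to
#' `[0, 1]`. For an orthogonal wavelet this equals plain pixel averaging; the
#' transform path is kept for fidelity to the workflow and as an extension
#' point for non-linear fusion rules.
#'
#' @param imgA,imgB `(H, W, 3)` arrays of identical size (register first).
#' @param wavelet wavelet family (see [dwt2()]).
#' @return fused `(H, W, 3)` array.
#' @export
dwtFuse <- function(imgA, imgB, wavelet = "haar") {
  if (!identical(dim(imgA), dim(imgB)))
    stop("images must have identical dimensions; register/resample first")
  out <- array(0, dim = dim(imgA))
  for (ch in 1:3) {
    bA <- dwt2(imgA[, , ch], wavelet)
    bB <- dwt2(imgB[, , ch], wavelet)
    fused <- list(a = (bA$a + bB$a) / 2, h = (bA$h + bB$h) / 2,
                  v = (bA$v + bB$v) / 2, d = (bA$d + bB$d) / 2,
                  wavelet = bA$wavelet, origDim = bA$origDim)
    out[, , ch] <- idwt2(fused)
  }
  clip01(out)
}

#' Least-squares affine transform from matched control points
#'
#' Estimates the 2-D transform mapping `moving` points onto `fixed` points
#' from at least three non-collinear correspondences. `type = "similarity"`
#' restricts to rotation + isotropic scale + translation (closed-form
#' least squares).
#'
#' @param moving,fixed `N x 2` matrices of matched `(x, y)` coordinates.
#' @param type `"affine"` (default) or `"similarity"`.
#' @return 3x3 homogeneous transform matrix with an `"rmse"` attribute (the
#'   matched-point residual).
#' @export
estimateTransform <- function(moving, fixed, type = c("affine", "similarity")) {
  type <- match.arg(type)
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed)) stop("point counts differ")
  if (nrow(moving) < 3L) stop("at least 3 point pairs are required")
  ctr <- scale(moving, scale = FALSE)
  if (qr(ctr)$rank < 2L) stop("control points are collinear")
  if (type == "affine") {
    X <- cbind(moving, 1)
    beta <- qr.solve(X, fixed)          # 3 x 2
    M <- rbind(t(beta), c(0, 0, 1))
  } else {
    mm <- colMeans(moving); mf <- colMeans(fixed)
    a <- sweep(moving, 2, mm); b <- sweep(fixed, 2, mf)
    num <- sum(a * b); cross <- sum(a[, 1] * b[, 2] - a[, 2] * b[, 1])
    den <- sum(a^2)
    s_cos <- num / den; s_sin <- cross / den
    A <- matrix(c(s_cos, s_sin, -s_sin, s_cos), 2, 2)
    t <- mf - A %*% mm
    M <- rbind(cbind(A, t), c(0, 0, 1))
  }
  pred <- t(M %*% t(cbind(moving, 1)))[, 1:2, drop = FALSE]
  attr(M, "rmse") <- sqrt(mean(rowSums((pred - fixed)^2)))
  M
}

#' Apply a homogeneous 2-D transform to points
#'
#' @param points `N x 2` matrix of `(x, y)` coordinates.
#' @param M 3x3 transform matrix.
#' @return transformed `N x 2` matrix.
#' @export
applyTransform <- function(points, M) {
  points <- as.matrix(points)
  out <- t(M %*% t(cbind(points, 1)))
  out[, 1:2, drop = FALSE]
}

#' Warp an RGB image with a transform (nearest-neighbour resampling)
#'
#' Inverse mapping: each output pixel takes the colour of the nearest source
#' pixel under `M^-1`; out-of-bounds pixels are black.
#'
#' @param img `(H, W, 3)` array.
#' @param M 3x3 transform from source to output frame.
#' @param outDim output `(H, W)` (defaults to the input size).
#' @return warped `(H, W, 3)` array.
#' @export
warpImage <- function(img, M, outDim = dim(img)[1:2]) {
  Minv <- solve(M)
  H <- outDim[1]; W <- outDim[2]
  xg <- rep(0:(W - 1), each = H)
  yg <- rep(0:(H - 1), times = W)
  src <- applyTransform(cbind(xg, yg), Minv)
  sx <- round(src[, 1]); sy <- round(src[, 2])
  ok <- sx >= 0 & sx < dim(img)[2] & sy >= 0 & sy < dim(img)[1]
  out <- array(0, dim = c(H, W, 3))
  di <- cbind(yg + 1L, xg + 1L)[ok, , drop = FALSE]
  si <- cbind(sy + 1L, sx + 1L)[ok, , drop = FALSE]
  for (ch in 1:3) {
    ini <- img[, , ch]
    o <- matrix(0, H, W)
    o[di] <- ini[si]
    out[, , ch] <- o
  }
  out
}

#' Keep only the cells of interest in a rendered cell heatmap
#'
#' Pixels carrying the positive pseudo-colour are preserved; everything else
#' becomes black background, so that fusion only superimposes the detected
#' cells onto the morphological-feature heatmap.
#'
#' @param img rendered heatmap `(H, W, 3)` array.
#' @param palette the rendering palette; must contain a `positive` colour.
#' @param tol per-channel colour tolerance.
#' @return thresholded `(H, W, 3)` array.
#' @export
thresholdCellHeatmap <- function(img, palette = heatmapPalette(),
                                 tol = 1 / 255) {
  if (is.null(palette$positive))
    stop("palette does not define the positive colour")
  keep <- abs(img[, , 1] - palette$positive[1]) <= tol &
    abs(img[, , 2] - palette$positive[2]) <= tol &
    abs(img[, , 3] - palette$positive[3]) <= tol
  out <- img
  for (ch in 1:3) out[, , ch] <- ifelse(keep, img[, , ch], 0)
  out
}

#' Register and fuse a cell heatmap onto an H&E feature heatmap
#'
#' The full bimodal pipeline: threshold the cell heatmap to the cells of
#' interest, estimate the affine transform from matched control points, warp
#' the thresholded map onto the H&E frame, and fuse by wavelet coefficient
#' averaging. Intermediate products are returned for audit.
#'
#' @param heMap H&E feature heatmap `(H, W, 3)` array (the fixed frame).
#' @param cellMap rendered cell heatmap `(H', W', 3)` array (moving frame).
#' @param controlPoints data.frame with `moving_x, moving_y, fixed_x,
#'   fixed_y`, or `NULL` for identity registration (sizes must then match).
#' @param palette cell-heatmap palette.
#' @param wavelet wavelet family.
#' @return list with `fused`, `transform`, `thresholded` and `warped`.
#' @export
fuseCase <- function(heMap, cellMap, controlPoints = NULL,
                     palette = heatmapPalette(), wavelet = "haar") {
  thr <- thresholdCellHeatmap(cellMap, palette)
  if (is.null(controlPoints)) {
    if (!identical(dim(heMap), dim(cellMap)))
      stop("identity registration requires equal dimensions")
    M <- diag(3)
    warped <- thr
  } else {
    M <- estimateTransform(cbind(controlPoints$moving_x, controlPoints$moving_y),
                           cbind(controlPoints$fixed_x, controlPoints$fixed_y))
    warped <- warpImage(thr, M, dim(heMap)[1:2])
  }
  list(fused = dwtFuse(heMap, warped, wavelet), transform = M,
       thresholded = thr, warped = warped)
}
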