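# Seeded generator of synthetic immunostained tissue tiles: pale eosinophilic
# background, blue-grey counterstained nuclei and brown perinuclear rings
# ("halo cells") of configurable stain intensity, with exported ground truth.

#' Default diagnostic H&E feature classes
#' @export
featureClassNames <- function() {
  c("normal_vessels", "normal_brain", "geographic_necrosis",
    "viable_tumour", "palisading_necrosis", "microvascular_proliferation")
}

defaultFeaturePalette <- function() {
  rbind(c(0.85, 0.10, 0.10),   # normal vessels
        c(0.20, 0.55, 0.20),   # normal brain
        c(0.35, 0.20, 0.55),   # geographic necrosis
        c(0.95, 0.75, 0.10),   # viable tumour
        c(0.10, 0.35, 0.75),   # palisading necrosis
        c(0.10, 0.75, 0.75))   # microvascular proliferation
}

# Chromogen ("DAB-brown") ring colour for a stain intensity I in [0, 1]:
# luminance is pinned to 1 - I, hue is high red/green, low blue.
brownRGB <- function(intensity) {
  L <- 1 - intensity
  pmin(1, L * c(1.35, 0.95, 0.55))
}

nucleusRGB <- function(shade = 1) pmin(1, shade * c(0.40, 0.44, 0.62))

# Draw per-cell intensities (and stratum labels) per the configured law.
drawIntensities <- function(config, n) {
  if (length(config@intensityStrata)) {
    w <- vapply(config@intensityStrata, function(s) s$weight %||% 1, 1)
    idx <- sample.int(length(w), n, replace = TRUE, prob = w / sum(w))
    intensity <- vapply(idx, function(i) {
      r <- config@intensityStrata[[i]]$range
      stats::runif(1, r[1], r[2])
    }, 1)
    names <- vapply(config@intensityStrata,
                    function(s) s$name %||% "stratum", "")
    list(intensity = intensity, stratum = names[idx])
  } else {
    r <- config@stainIntensityRange
    list(intensity = stats::runif(n, r[1], r[2]),
         stratum = rep(NA_character_, n))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rejection-sample `n` centres in [lo, hi]^2 with minimum pairwise distance
# `minSep`; optional per-position acceptance weight via `weightFun(x, y)`.
sampleCentres <- function(n, xlim, ylim, minSep, weightFun = NULL,
                          maxTries = 4000L * max(1L, n)) {
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    tries <- tries + 1L
    if (tries > maxTries)
      stop(sprintf(paste0("infeasible packing: placed %d of %d cells; cannot ",
                          "satisfy minimum centre separation %.1f px within ",
                          "[%d, %d] x [%d, %d]"),
                   length(xs), n, minSep, xlim[1], xlim[2], ylim[1], ylim[2]))
    x <- round(stats::runif(1, xlim[1], xlim[2]))
    y <- round(stats::runif(1, ylim[1], ylim[2]))
    if (!is.null(weightFun) && stats::runif(1) > weightFun(x, y)) next
    if (length(xs) &&
        min((xs - x)^2 + (ys - y)^2) < minSep^2) next
    xs <- c(xs, x); ys <- c(ys, y)
  }
  cbind(x = xs, y = ys)
}

# Paint a filled disc (d <= r) or annulus (rIn <= d <= r) onto `img`.
paintRing <- function(img, cx, cy, rOut, rIn, rgb, jitterSd = 0) {
  H <- dim(img)[1]; W <- dim(img)[2]
  y0 <- max(0, floor(cy - rOut)); y1 <- min(H - 1, ceiling(cy + rOut))
  x0 <- max(0, floor(cx - rOut)); x1 <- min(W - 1, ceiling(cx + rOut))
  ys <- y0:y1; xs <- x0:x1
  d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  sel <- d2 <= rOut^2 & d2 >= rIn^2
  if (!any(sel)) return(img)
  jit <- if (jitterSd > 0) stats::rnorm(sum(sel), 0, jitterSd) else 0
  for (ch in 1:3) {
    block <- img[ys + 1, xs + 1, ch]
    block[sel] <- clip01(rgb[ch] + jit)
    img[ys + 1, xs + 1, ch] <- block
  }
  img
}

renderBackground <- function(H, W, noiseSd) {
  base <- c(0.96, 0.92, 0.94)
  # low-frequency eosinophilic texture shared across channels
  tex <- gaussianBlur(matrix(stats::rnorm(H * W, 0, 1), H, W), 6)
  tex <- 0.4 * tex / max(stats::sd(tex), 1e-9)
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3)
    img[, , ch] <- clip01(base[ch] - 0.03 * abs(tex) +
                            stats::rnorm(H * W, 0, noiseSd))
  img
}

#' Generate one synthetic immunostained tile with ground truth
#'
#' Renders a pale stained-tissue background with counterstained nuclei and
#' `nCells` brown perinuclear rings at non-overlapping centres, and returns
#' the tile together with its positive and negative mark points. The
#' recorded per-cell `intensity` equals one minus the luminance of the ring
#' pixels, so it can be read back from the rendered raster. All randomness
#' derives from one seed: identical configuration and seed give bit-identical
#' output.
#'
#' @param config a [SyntheticConfig-class].
#' @param caseId,tileId identifiers stamped on the tile and marks.
#' @param origin 0-based offset of the tile within its case canvas.
#' @param seed overrides `config@seed` (used when a case derives per-tile
#'   seeds).
#' @param weightFun optional function `(x, y) -> [0, 1]` thinning cell
#'   placement (used for per-region density control).
#' @return `list(tile = ImageTile, marks = data.frame)` where `marks` has
#'   columns `case_id, tile_id, x, y, label, intensity, stratum`.
#' @export
generateTile <- function(config, caseId = "case1", tileId = "tile1",
                         origin = c(0, 0), seed = config@seed,
                         weightFun = NULL) {
  validObject(config)
  W <- config@tileWidth; H <- config@tileHeight
  withSeed(seed, {
    img <- renderBackground(H, W, config@backgroundNoiseSd)

    # counterstained nuclei: a mix of scattered and clustered
    nNuc <- config@nucleiDensity
    nucXY <- NULL
    if (nNuc > 0L) {
      nClust <- max(1L, nNuc %/% 10L)
      cx <- stats::runif(nClust, 0, W - 1)
      cy <- stats::runif(nClust, 0, H - 1)
      nScatter <- round(0.6 * nNuc)
      sx <- stats::runif(nScatter, 0, W - 1)
      sy <- stats::runif(nScatter, 0, H - 1)
      k <- sample.int(nClust, nNuc - nScatter, replace = TRUE)
      gx <- pmin(pmax(cx[k] + stats::rnorm(nNuc - nScatter, 0, 12), 0), W - 1)
      gy <- pmin(pmax(cy[k] + stats::rnorm(nNuc - nScatter, 0, 12), 0), H - 1)
      nucXY <- cbind(c(sx, gx), c(sy, gy))
      for (i in seq_len(nNuc)) {
        r <- stats::runif(1, 3, 6)
        img <- paintRing(img, nucXY[i, 1], nucXY[i, 2], r, 0,
                         nucleusRGB(stats::runif(1, 0.75, 1.1)),
                         jitterSd = 0.015)
      }
    }

    # positive "halo" cells
    n <- config@nCells
    marks <- data.frame(case_id = character(0), tile_id = character(0),
                        x = integer(0), y = integer(0), label = character(0),
                        intensity = numeric(0), stratum = character(0),
                        stringsAsFactors = FALSE)
    if (n > 0L) {
      minSep <- 2 * max(config@cellRadiusRange)
      centres <- sampleCentres(n, c(32, W - 32), c(32, H - 32), minSep,
                               weightFun = weightFun)
      law <- drawIntensities(config, n)
      for (i in seq_len(n)) {
        rOut <- stats::runif(1, config@cellRadiusRange[1],
                             config@cellRadiusRange[2])
        rIn <- rOut - config@haloRingWidth
        # perinuclear look: counterstained nucleus inside the chromogen ring
        img <- paintRing(img, centres[i, 1], centres[i, 2],
                         max(0, rIn - 0.5), 0, nucleusRGB(0.95),
                         jitterSd = 0.015)
        img <- paintRing(img, centres[i, 1], centres[i, 2], rOut, rIn,
                         brownRGB(law$intensity[i]), jitterSd = 0.01)
      }
      marks <- data.frame(case_id = caseId, tile_id = tileId,
                          x = as.integer(centres[, 1]),
                          y = as.integer(centres[, 2]),
                          label = "positive", intensity = law$intensity,
                          stratum = law$stratum, stringsAsFactors = FALSE)
    }

    # negative marks: plain background and nuclei clusters, far from cells
    nNeg <- config@nNegatives
    if (nNeg > 0L) {
      farFromCells <- function(x, y) {
        if (n == 0L) return(TRUE)
        min((marks$x - x)^2 + (marks$y - y)^2) >= 64^2
      }
      negx <- integer(0); negy <- integer(0); tries <- 0L
      # prefer nuclei locations for half the negatives
      cand <- if (!is.null(nucXY)) nucXY[sample.int(nrow(nucXY)), , drop = FALSE]
              else matrix(numeric(0), 0, 2)
      ci <- 1L
      while (length(negx) < nNeg && tries < 200L * nNeg) {
        tries <- tries + 1L
        useNucleus <- (length(negx) %% 2L == 0L) && ci <= nrow(cand)
        if (useNucleus) {
          x <- round(cand[ci, 1]); y <- round(cand[ci, 2]); ci <- ci + 1L
        } else {
          x <- round(stats::runif(1, 32, W - 32))
          y <- round(stats::runif(1, 32, H - 32))
        }
        if (x < 32 || x > W - 32 || y < 32 || y > H - 32) next
        if (!farFromCells(x, y)) next
        negx <- c(negx, x); negy <- c(negy, y)
      }
      if (length(negx))
        marks <- rbind(marks,
                       data.frame(case_id = caseId, tile_id = tileId,
                                  x = as.integer(negx), y = as.integer(negy),
                                  label = "negative", intensity = NA_real_,
                                  stratum = NA_character_,
                                  stringsAsFactors = FALSE))
    }

    tile <- imageTile(img, caseId = caseId, tileId = tileId, origin = origin,
                      micronsPerPixel = config@micronsPerPixel)
    list(tile = tile, marks = marks)
  })
}

#' Build a morphological feature map for a case canvas
#'
#' Divides the canvas into equal-width vertical bands, one per class, at a
#' raster resolution of `scale` case pixels per raster pixel.
#'
#' @param caseWidth,caseHeight case canvas size in pixels.
#' @param classes class names (default the six diagnostic features).
#' @param palette `K x 3` RGB matrix, one distinct colour per class.
#' @param scale case pixels per raster pixel (defaults to the inference
#'   stride so the raster is at heatmap resolution).
#' @param micronsPerPixel physical scale of the case pixels.
#' @return a [FeatureMap-class].
#' @export
featureMapSpec <- function(caseWidth, caseHeight,
                           classes = featureClassNames(),
                           palette = defaultFeaturePalette(),
                           scale = 10, micronsPerPixel = 0.25) {
  nx <- ceiling(caseWidth / scale)
  ny <- ceiling(caseHeight / scale)
  band <- ceiling(nx / length(classes))
  raster <- matrix(0L, ny, nx)
  for (j in seq_len(nx))
    raster[, j] <- min(length(classes), (j - 1L) %/% band + 1L)
  new("FeatureMap", raster = raster, classes = classes,
      palette = palette[seq_along(classes), , drop = FALSE],
      scale = scale, micronsPerPixel = micronsPerPixel)
}

#' Look up the feature class of case-frame coordinates
#'
#' Nearest-pixel (block) lookup: case pixel `(x, y)` belongs to raster cell
#' `floor(x / scale), floor(y / scale)`.
#'
#' @param featureMap a [FeatureMap-class].
#' @param x,y 0-based case-frame coordinates.
#' @return character vector of class names, `"unassigned"` outside the
#'   raster.
#' @export
featureClassAt <- function(featureMap, x, y) {
  j <- floor(x / featureMap@scale) + 1L
  i <- floor(y / featureMap@scale) + 1L
  ok <- i >= 1L & i <= nrow(featureMap@raster) &
    j >= 1L & j <= ncol(featureMap@raster)
  out <- rep("unassigned", length(x))
  out[ok] <- featureMap@classes[featureMap@raster[cbind(i[ok], j[ok])]]
  out
}

#' Generate a synthetic case: tiles, marks, feature map and control points
#'
#' Lays `nTiles` tiles on a near-square grid forming one case canvas, builds
#' (or accepts) a companion feature map at heatmap resolution, and places
#' cells with per-class relative densities via thinned rejection sampling, so
#' expected per-class counts follow `classDensity` times region area.
#' Pre-matched registration control points (identity correspondence between
#' the cell-heatmap frame and the feature-map frame) are emitted alongside.
#'
#' @param config a [SyntheticConfig-class] (per-tile settings).
#' @param featureMap optional [FeatureMap-class]; built by [featureMapSpec()]
#'   when `NULL`.
#' @param nTiles number of tiles (at least 1; 4 mirrors one whole-slide
#'   image).
#' @param caseId case identifier.
#' @param classDensity named relative placement weights per feature class
#'   (default: all equal).
#' @return `list(tiles, marks, featureMap, controlPoints)`; `marks` gains
#'   case-frame columns `case_x`, `case_y`.
#' @export
generateCase <- function(config, featureMap = NULL, nTiles = 4L,
                         caseId = "case1", classDensity = NULL) {
  if (nTiles < 1L) stop("nTiles must be at least 1")
  ncols <- ceiling(sqrt(nTiles))
  nrows <- ceiling(nTiles / ncols)
  caseW <- ncols * config@tileWidth
  caseH <- nrows * config@tileHeight
  if (is.null(featureMap))
    featureMap <- featureMapSpec(caseW, caseH,
                                 micronsPerPixel = config@micronsPerPixel)
  if (is.null(classDensity))
    classDensity <- stats::setNames(rep(1, length(featureMap@classes)),
                                    featureMap@classes)

  origins <- cbind(((seq_len(nTiles) - 1L) %% ncols) * config@tileWidth,
                   ((seq_len(nTiles) - 1L) %/% ncols) * config@tileHeight)
  # allocate the case's total cell budget across tiles in proportion to the
  # mean placement weight of each tile's region, so per-class expected
  # counts follow density x area even when classes segregate by tile
  sc <- featureMap@scale
  tileMeanW <- vapply(seq_len(nTiles), function(t) {
    ri <- (origins[t, 2] %/% sc + 1L):
      min(nrow(featureMap@raster), (origins[t, 2] + config@tileHeight) %/% sc)
    ci <- (origins[t, 1] %/% sc + 1L):
      min(ncol(featureMap@raster), (origins[t, 1] + config@tileWidth) %/% sc)
    mean(classDensity[featureMap@classes[featureMap@raster[ri, ci]]])
  }, 1)
  nTotal <- config@nCells * nTiles
  tileCells <- withSeed(deriveSeed(config@seed, 7777L), {
    if (nTotal > 0L && sum(tileMeanW) > 0)
      as.integer(stats::rmultinom(1, nTotal, tileMeanW / sum(tileMeanW)))
    else rep(0L, nTiles)
  })

  tiles <- vector("list", nTiles)
  marks <- NULL
  for (t in seq_len(nTiles)) {
    ox <- origins[t, 1]
    oy <- origins[t, 2]
    maxW <- max(classDensity)
    wf <- function(x, y) {
      cls <- featureClassAt(featureMap, ox + x, oy + y)
      if (cls == "unassigned") return(0)
      unname(classDensity[cls] / maxW)
    }
    cfgT <- config
    cfgT@nCells <- tileCells[t]
    g <- generateTile(cfgT, caseId = caseId,
                      tileId = sprintf("tile%d", t), origin = c(ox, oy),
                      seed = deriveSeed(config@seed, t), weightFun = wf)
    tiles[[t]] <- g$tile
    if (nrow(g$marks)) {
      g$marks$case_x <- g$marks$x + ox
      g$marks$case_y <- g$marks$y + oy
    } else {
      g$marks$case_x <- integer(0); g$marks$case_y <- integer(0)
    }
    marks <- rbind(marks, g$marks)
  }

  controlPoints <- data.frame(
    moving_x = c(0, caseW - 1, 0, caseW - 1, caseW / 2),
    moving_y = c(0, 0, caseH - 1, caseH - 1, caseH / 2),
    fixed_x = c(0, caseW - 1, 0, caseW - 1, caseW / 2),
    fixed_y = c(0, 0, caseH - 1, caseH - 1, caseH / 2))

  list(tiles = tiles, marks = marks, featureMap = featureMap,
       controlPoints = controlPoints)
}

#' Render a feature map to an RGB image at case resolution
#'
#' @param featureMap a [FeatureMap-class].
#' @param caseWidth,caseHeight output size in case pixels (defaults to the
#'   raster extent times `scale`).
#' @return `(H, W, 3)` array.
#' @export
renderFeatureMap <- function(featureMap,
                             caseWidth = ncol(featureMap@raster) * featureMap@scale,
                             caseHeight = nrow(featureMap@raster) * featureMap@scale) {
  s <- featureMap@scale
  xs <- pmin(floor((seq_len(caseWidth) - 1) / s) + 1, ncol(featureMap@raster))
  ys <- pmin(floor((seq_len(caseHeight) - 1) / s) + 1, nrow(featureMap@raster))
  idx <- featureMap@raster[ys, xs, drop = FALSE]
  img <- array(0, dim = c(caseHeight, caseWidth, 3))
  for (ch in 1:3)
    img[, , ch] <- matrix(featureMap@palette[idx, ch], caseHeight, caseWidth)
  img
}
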