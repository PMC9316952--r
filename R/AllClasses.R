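#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib bifocal, .registration = TRUE
NULL

#' Configuration of the synthetic stained-tissue generator
#'
#' Describes one simulated immunostained tile: geometry, the number and size
#' of immunoreactive ring cells ("halo cells": a brown chromogen ring around a
#' counterstained nucleus), the stain-intensity law, counterstain nuclei
#' density, background noise, the physical pixel size and the seed that makes
#' the whole tile reproducible.
#'
#' @slot tileWidth,tileHeight tile size in pixels (each at least 128).
#' @slot nCells number of ring cells per tile.
#' @slot cellRadiusRange outer ring radius range in pixels.
#' @slot haloRingWidth radial ring thickness in pixels.
#' @slot stainIntensityRange per-cell stain intensity range, a subset of
#'   `[0, 1]`; intensity is defined as 1 minus the relative luminance of the
#'   ring pixels, so stronger staining means higher signal.
#' @slot intensityStrata optional list of strata, each a
#'   `list(name=, range=, weight=)`; when non-empty it replaces
#'   `stainIntensityRange` and the stratum of every cell is recorded.
#' @slot backgroundNoiseSd per-pixel Gaussian noise s.d. of the background.
#' @slot nucleiDensity number of counterstained (ring-free) nuclei per tile.
#' @slot nNegatives number of negative mark points sampled per tile.
#' @slot micronsPerPixel physical scale in micrometres per pixel.
#' @slot seed integer seed; identical seeds give bit-identical tiles.
#' @export
setClass("SyntheticConfig", representation(
  tileWidth = "integer", tileHeight = "integer",
  nCells = "integer", cellRadiusRange = "numeric", haloRingWidth = "numeric",
  stainIntensityRange = "numeric", intensityStrata = "list",
  backgroundNoiseSd = "numeric", nucleiDensity = "integer",
  nNegatives = "integer", micronsPerPixel = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@tileWidth < 128L || object@tileHeight < 128L)
    msg <- c(msg, "tile dimensions must be at least 128 px")
  if (object@nCells < 0L) msg <- c(msg, "nCells must be non-negative")
  if (length(object@cellRadiusRange) != 2L ||
      any(object@cellRadiusRange <= 0) ||
      diff(object@cellRadiusRange) < 0)
    msg <- c(msg, "cellRadiusRange must be an increasing positive pair")
  if (object@haloRingWidth <= 0 ||
      object@haloRingWidth >= min(object@cellRadiusRange))
    msg <- c(msg, "haloRingWidth must be positive and below the minimum radius")
  r <- object@stainIntensityRange
  if (length(r) != 2L || r[1] < 0 || r[2] > 1 || r[1] > r[2])
    msg <- c(msg, "stainIntensityRange must be an ordered subset of [0, 1]")
  for (s in object@intensityStrata) {
    if (!is.list(s) || is.null(s$range) || s$range[1] < 0 || s$range[2] > 1)
      msg <- c(msg, "each intensity stratum needs a range inside [0, 1]")
  }
  if (object@backgroundNoiseSd < 0) msg <- c(msg, "backgroundNoiseSd < 0")
  if (object@micronsPerPixel <= 0) msg <- c(msg, "micronsPerPixel must be > 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn SyntheticConfig Constructor with 40x-scan-like defaults.
#' @param tileWidth,tileHeight,nCells,cellRadiusRange,haloRingWidth,stainIntensityRange,intensityStrata,backgroundNoiseSd,nucleiDensity,nNegatives,micronsPerPixel,seed see slots.
#' @export
syntheticConfig <- function(tileWidth = 512L, tileHeight = 512L, nCells = 25L,
                            cellRadiusRange = c(8, 14), haloRingWidth = 4,
                            stainIntensityRange = c(0.55, 0.9),
                            intensityStrata = list(),
                            backgroundNoiseSd = 0.02, nucleiDensity = 150L,
                            nNegatives = nCells,
                            micronsPerPixel = 0.25, seed = 1L) {
  new("SyntheticConfig",
      tileWidth = as.integer(tileWidth), tileHeight = as.integer(tileHeight),
      nCells = as.integer(nCells), cellRadiusRange = as.numeric(cellRadiusRange),
      haloRingWidth = as.numeric(haloRingWidth),
      stainIntensityRange = as.numeric(stainIntensityRange),
      intensityStrata = intensityStrata,
      backgroundNoiseSd = as.numeric(backgroundNoiseSd),
      nucleiDensity = as.integer(nucleiDensity),
      nNegatives = as.integer(nNegatives),
      micronsPerPixel = as.numeric(micronsPerPixel), seed = as.integer(seed))
}

#' An RGB image tile with physical scale and case provenance
#'
#' @slot array `(H, W, 3)` numeric array with values in `[0, 1]`.
#' @slot caseId,tileId identifiers of the source case and tile.
#' @slot origin length-2 numeric, the 0-based `(x, y)` offset of the tile's
#'   upper-left pixel within its case canvas.
#' @slot micronsPerPixel physical scale in micrometres per pixel.
#' @export
setClass("ImageTile", representation(
  array = "array", caseId = "character", tileId = "character",
  origin = "numeric", micronsPerPixel = "numeric"))

setValidity("ImageTile", function(object) {
  d <- dim(object@array)
  if (length(d) != 3L || d[3] != 3L) return("array must be (H, W, 3)")
  if (min(object@array) < 0 || max(object@array) > 1)
    return("pixel values must lie in [0, 1]")
  if (length(object@origin) != 2L) return("origin must have length 2")
  if (object@micronsPerPixel <= 0) return("micronsPerPixel must be positive")
  TRUE
})

#' @describeIn ImageTile Constructor.
#' @param array,caseId,tileId,origin,micronsPerPixel see slots.
#' @export
imageTile <- function(array, caseId = "case1", tileId = "tile1",
                      origin = c(0, 0), micronsPerPixel = 0.25) {
  new("ImageTile", array = array, caseId = caseId, tileId = tileId,
      origin = as.numeric(origin), micronsPerPixel = micronsPerPixel)
}

#' A set of co-centred bifocal patch pairs
#'
#' The unit fed to the bifocal classifier: for every marked or scanned centre,
#' a narrow (cell-focused, 32x32) and a wide (tissue-context, 64x64) RGB crop
#' sharing that centre; the narrow crop is always the central sub-window of
#' the wide crop.
#'
#' @slot narrow `(s, s, 3, N)` array of narrow crops.
#' @slot wide `(2s, 2s, 3, N)` array of wide crops.
#' @slot labels factor with levels `negative`, `positive` (may hold `NA` for
#'   unlabelled inference patches).
#' @slot centres `N x 2` matrix of 0-based `(x, y)` centres.
#' @slot caseIds,tileIds provenance, one entry per pair.
#' @export
setClass("BifocalPatchSet", representation(
  narrow = "array", wide = "array", labels = "factor",
  centres = "matrix", caseIds = "character", tileIds = "character"))

setValidity("BifocalPatchSet", function(object) {
  dn <- dim(object@narrow); dw <- dim(object@wide)
  if (length(dn) != 4L || length(dw) != 4L)
    return("narrow and wide must be 4-d arrays (H, W, 3, N)")
  if (dw[1] != 2L * dn[1] || dw[2] != 2L * dn[2])
    return("wide crops must be twice the narrow crop size")
  n <- dn[4]
  if (dw[4] != n || length(object@labels) != n ||
      nrow(object@centres) != n || length(object@caseIds) != n ||
      length(object@tileIds) != n)
    return("inconsistent pair count across slots")
  if (!identical(levels(object@labels), c("negative", "positive")))
    return("labels must have levels negative, positive")
  TRUE
})

#' A stride-resolution lattice of positive-class scores over a tile
#'
#' @slot scores `ny x nx` matrix of positive-class probabilities; entry
#'   `[i, j]` belongs to the sliding-window centre
#'   `(originOffset + (j-1)*stride, originOffset + (i-1)*stride)` in 0-based
#'   tile pixels.
#' @slot stride lattice spacing in pixels.
#' @slot originOffset centre coordinate of the first window (half the wide
#'   patch size).
#' @slot caseId,tileId provenance.
#' @slot tileOrigin 0-based offset of the tile within its case.
#' @slot micronsPerPixel physical scale.
#' @export
setClass("HeatmapGrid", representation(
  scores = "matrix", stride = "integer", originOffset = "integer",
  caseId = "character", tileId = "character", tileOrigin = "numeric",
  micronsPerPixel = "numeric"))

setValidity("HeatmapGrid", function(object) {
  s <- object@scores
  if (length(s) && (min(s) < 0 || max(s) > 1))
    return("scores must lie in [0, 1]")
  if (object@stride < 1L) return("stride must be >= 1")
  TRUE
})

#' A bifocal convolutional classifier
#'
#' Two convolutional sub-nets (one per focal size), global-average-pooled
#' branch features concatenated into a hidden layer and a 2-way softmax.
#'
#' @slot config the [bcnnConfig()] list used to build the model.
#' @slot params named list of weight matrices and bias vectors.
#' @slot trained logical flag.
#' @slot history per-epoch training log (`data.frame`).
#' @export
setClass("BCNNModel", representation(
  config = "list", params = "list", trained = "logical",
  history = "data.frame"))

#' Per-case Otsu-statistic summary and acceptance threshold
#'
#' Holds the per-patch Otsu statistics sigma of one whole-slide image (case),
#' their count and sum, the minimum statistic and the acceptance threshold
#' `T = mean(sigma) - min(sigma)` used to split detections into discriminable
#' and less-discriminable cells.
#'
#' @slot sigma numeric vector of per-patch Otsu statistics in `[0, 1]`.
#' @slot n number of patches.
#' @slot sigmaSum sum of the statistics.
#' @slot tMin minimum statistic.
#' @slot T acceptance threshold (mean minus minimum, always `>= 0`).
#' @export
setClass("ThresholdSummary", representation(
  sigma = "numeric", n = "integer", sigmaSum = "numeric",
  tMin = "numeric", T = "numeric"))

setValidity("ThresholdSummary", function(object) {
  if (object@n != length(object@sigma)) return("n must equal length(sigma)")
  if (object@n < 1L) return("at least one sigma value is required")
  if (abs(object@sigmaSum - sum(object@sigma)) > 1e-9)
    return("sigmaSum must equal sum(sigma)")
  if (abs(object@tMin - min(object@sigma)) > 1e-12)
    return("tMin must equal min(sigma)")
  if (object@T < -1e-12) return("T must be non-negative")
  TRUE
})

#' Classifier evaluation report
#'
#' @slot confusion 2x2 count matrix (rows: truth, columns: prediction).
#' @slot accuracy,precision,recall,specificity,f1 fractions in `[0, 1]`.
#' @slot roc data.frame of ROC sweep points (`threshold`, `fpr`, `tpr`).
#' @slot auc area under the ROC curve (trapezoid rule).
#' @slot threshold decision threshold used for the confusion matrix.
#' @slot n number of evaluated pairs.
#' @export
setClass("EvalReport", representation(
  confusion = "matrix", accuracy = "numeric", precision = "numeric",
  recall = "numeric", specificity = "numeric", f1 = "numeric",
  roc = "data.frame", auc = "numeric", threshold = "numeric", n = "integer"))

#' A categorical morphological-feature raster with palette
#'
#' Case-level map assigning every raster pixel one diagnostic H&E feature
#' class (e.g. viable tumour, necrosis, vessels), stored at a coarser scale
#' than the tiles (one raster pixel covers `scale` x `scale` tile pixels).
#'
#' @slot raster integer matrix of class indices (1-based into `classes`).
#' @slot classes character vector of class names.
#' @slot palette `K x 3` matrix of RGB colours in `[0, 1]`, one row per class;
#'   rows must be distinct (injective palette).
#' @slot scale case pixels per raster pixel.
#' @slot micronsPerPixel physical scale of the *case* pixels.
#' @export
setClass("FeatureMap", representation(
  raster = "matrix", classes = "character", palette = "matrix",
  scale = "numeric", micronsPerPixel = "numeric"))

setValidity("FeatureMap", function(object) {
  K <- length(object@classes)
  v <- object@raster
  if (length(v) && (min(v) < 1L || max(v) > K))
    return("raster values must index into classes")
  if (nrow(object@palette) != K || ncol(object@palette) != 3L)
    return("palette must be K x 3")
  if (anyDuplicated(apply(object@palette, 1, paste, collapse = ",")))
    return("palette must be injective (distinct colour per class)")
  if (object@scale <= 0) return("scale must be positive")
  TRUE
})
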