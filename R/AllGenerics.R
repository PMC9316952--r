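#' Accessors for bifocal data containers
#'
#' Small accessor generics: `tileArray()` returns the pixel array of an
#' [ImageTile-class], `caseId()`/`tileId()` its provenance, `mpp()` the
#' physical scale of a tile, grid or feature map, `scores()` the lattice of a
#' [HeatmapGrid-class], `narrowPatches()`/`widePatches()`/`pairLabels()`/
#' `pairCentres()` the slots of a [BifocalPatchSet-class], and
#' `acceptanceT()`/`sigmaValues()` the components of a
#' [ThresholdSummary-class].
#'
#' @param x an object of the documented class.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tileArray", function(x) standardGeneric("tileArray"))
#' @rdname accessors
#' @export
setGeneric("caseId", function(x) standardGeneric("caseId"))
#' @rdname accessors
#' @export
setGeneric("tileId", function(x) standardGeneric("tileId"))
#' @rdname accessors
#' @export
setGeneric("mpp", function(x) standardGeneric("mpp"))
#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("narrowPatches", function(x) standardGeneric("narrowPatches"))
#' @rdname accessors
#' @export
setGeneric("widePatches", function(x) standardGeneric("widePatches"))
#' @rdname accessors
#' @export
setGeneric("pairLabels", function(x) standardGeneric("pairLabels"))
#' @rdname accessors
#' @export
setGeneric("pairCentres", function(x) standardGeneric("pairCentres"))
#' @rdname accessors
#' @export
setGeneric("acceptanceT", function(x) standardGeneric("acceptanceT"))
#' @rdname accessors
#' @export
setGeneric("sigmaValues", function(x) standardGeneric("sigmaValues"))

#' @rdname accessors
setMethod("tileArray", "ImageTile", function(x) x@array)
#' @rdname accessors
setMethod("caseId", "ImageTile", function(x) x@caseId)
#' @rdname accessors
setMethod("tileId", "ImageTile", function(x) x@tileId)
#' @rdname accessors
setMethod("mpp", "ImageTile", function(x) x@micronsPerPixel)
#' @rdname accessors
setMethod("mpp", "HeatmapGrid", function(x) x@micronsPerPixel)
#' @rdname accessors
setMethod("mpp", "FeatureMap", function(x) x@micronsPerPixel)
#' @rdname accessors
setMethod("scores", "HeatmapGrid", function(x) x@scores)
#' @rdname accessors
setMethod("narrowPatches", "BifocalPatchSet", function(x) x@narrow)
#' @rdname accessors
setMethod("widePatches", "BifocalPatchSet", function(x) x@wide)
#' @rdname accessors
setMethod("pairLabels", "BifocalPatchSet", function(x) x@labels)
#' @rdname accessors
setMethod("pairCentres", "BifocalPatchSet", function(x) x@centres)
#' @rdname accessors
setMethod("acceptanceT", "ThresholdSummary", function(x) x@T)
#' @rdname accessors
setMethod("sigmaValues", "ThresholdSummary", function(x) x@sigma)

#' @describeIn accessors Tile dimensions as `(H, W, 3)`.
#' @export
setMethod("dim", "ImageTile", function(x) dim(x@array))

#' @describeIn accessors Number of pairs in a patch set.
#' @export
setMethod("length", "BifocalPatchSet", function(x) dim(x@narrow)[4])

#' Subset a patch set
#'
#' @param x a [BifocalPatchSet-class].
#' @param i index vector of pairs to keep.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "BifocalPatchSet", function(x, i, j, ..., drop = FALSE) {
  new("BifocalPatchSet",
      narrow = x@narrow[, , , i, drop = FALSE],
      wide = x@wide[, , , i, drop = FALSE],
      labels = x@labels[i],
      centres = x@centres[i, , drop = FALSE],
      caseIds = x@caseIds[i], tileIds = x@tileIds[i])
})

setMethod("show", "ImageTile", function(object) {
  d <- dim(object@array)
  cat(sprintf("ImageTile %s/%s: %d x %d px, %.3g um/px, origin (%g, %g)\n",
              object@caseId, object@tileId, d[2], d[1],
              object@micronsPerPixel, object@origin[1], object@origin[2]))
})

setMethod("show", "BifocalPatchSet", function(object) {
  n <- length(object)
  tab <- table(object@labels)
  cat(sprintf("BifocalPatchSet: %d pairs (%dx%d / %dx%d), %d positive, %d negative\n",
              n, dim(object@narrow)[1], dim(object@narrow)[2],
              dim(object@wide)[1], dim(object@wide)[2],
              tab[["positive"]], tab[["negative"]]))
})

setMethod("show", "HeatmapGrid", function(object) {
  cat(sprintf("HeatmapGrid %s/%s: %d x %d lattice, stride %d, offset %d\n",
              object@caseId, object@tileId, nrow(object@scores),
              ncol(object@scores), object@stride, object@originOffset))
})

setMethod("show", "BCNNModel", function(object) {
  cfg <- object@config
  cat(sprintf("BCNNModel: branches %dx%d / %dx%d, channels %s, hidden %d (%s)\n",
              cfg$narrowSize, cfg$narrowSize, cfg$wideSize, cfg$wideSize,
              paste(cfg$channels, collapse = "-"), cfg$hidden,
              if (object@trained) "trained" else "untrained"))
})

setMethod("show", "ThresholdSummary", function(object) {
  cat(sprintf("ThresholdSummary: N = %d, mean sigma = %.4f, min = %.4f, T = %.4f\n",
              object@n, object@sigmaSum / object@n, object@tMin, object@T))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: n = %d, accuracy %.3f, precision %.3f, recall %.3f, F1 %.3f, AUC %.3f\n",
              object@n, object@accuracy, object@precision, object@recall,
              object@f1, object@auc))
  print(object@confusion)
})

setMethod("show", "FeatureMap", function(object) {
  cat(sprintf("FeatureMap: %d x %d raster, %d classes, %g px/cell, %.3g um/px\n",
              nrow(object@raster), ncol(object@raster),
              length(object@classes), object@scale, object@micronsPerPixel))
})
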