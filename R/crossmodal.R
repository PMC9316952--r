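# Cross-modality reporting: assign each retained cell the morphological
# feature class at its registered location and tabulate per-feature counts
# and densities.

#' Assign feature classes to detected cells
#'
#' Maps each cell's case-frame coordinate into the feature-map frame with
#' `transform` (identity by default) and looks up the class of the nearest
#' raster pixel. Cells mapping outside the raster are labelled
#' `"unassigned"` and excluded from density denominators downstream.
#'
#' @param cells data.frame with `case_x`, `case_y` columns (e.g. retained
#'   detections).
#' @param featureMap a [FeatureMap-class].
#' @param transform optional 3x3 matrix mapping cell coordinates into the
#'   feature-map case frame.
#' @return the input with a `feature_class` column added.
#' @export
assignClasses <- function(cells, featureMap, transform = NULL) {
  if (!all(c("case_x", "case_y") %in% names(cells)))
    stop("cells need case_x / case_y columns")
  xy <- cbind(cells$case_x, cells$case_y)
  if (!is.null(transform)) xy <- applyTransform(xy, transform)
  cells$feature_class <- if (nrow(cells))
    featureClassAt(featureMap, xy[, 1], xy[, 2]) else character(0)
  cells
}

#' Per-feature cell counts and densities
#'
#' Counts assigned cells per morphological feature class and divides by the
#' class's region area (`pixel count x (scale x mpp)^2`, in mm^2). Classes
#' with zero raster area are omitted with a warning; unassigned cells are
#' reported in an attribute.
#'
#' @param assignments data.frame from [assignClasses()].
#' @param featureMap a [FeatureMap-class].
#' @param micronsPerPixel physical scale of the case pixels (defaults to the
#'   feature map's).
#' @return data.frame with columns `feature`, `n_cells`, `area_mm2`,
#'   `density_per_mm2` (one row per class present in the raster), with
#'   attribute `n_unassigned`.
#' @export
densityReport <- function(assignments, featureMap,
                          micronsPerPixel = mpp(featureMap)) {
  if (micronsPerPixel <= 0) stop("micronsPerPixel must be positive")
  umPerRasterPx <- featureMap@scale * micronsPerPixel
  pxArea <- tabulate(featureMap@raster, nbins = length(featureMap@classes))
  areaMm2 <- pxArea * (umPerRasterPx / 1000)^2
  counts <- table(factor(assignments$feature_class,
                         levels = featureMap@classes))
  zero <- areaMm2 <= 0
  if (any(zero & counts > 0))
    warning("classes with zero area omitted: ",
            paste(featureMap@classes[zero & counts > 0], collapse = ", "))
  else if (any(zero))
    warning("classes with zero area omitted: ",
            paste(featureMap@classes[zero], collapse = ", "))
  keep <- !zero
  out <- data.frame(feature = featureMap@classes[keep],
                    n_cells = as.integer(counts[keep]),
                    area_mm2 = areaMm2[keep],
                    density_per_mm2 = as.integer(counts[keep]) / areaMm2[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_unassigned") <-
    sum(assignments$feature_class == "unassigned")
  out
}
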