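# Raster I/O (PNG) and feature-map serialization.

#' Read / write RGB images as PNG
#'
#' @param img `(H, W, 3)` array in `[0, 1]`.
#' @param path file path.
#' @return `readImagePNG` returns an `(H, W, 3)` array; grayscale or RGBA
#'   files are expanded/truncated to 3 channels.
#' @export
writeImagePNG <- function(img, path) {
  png::writePNG(clip01(img), path)
  invisible(path)
}

#' @rdname writeImagePNG
#' @export
readImagePNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write / read an ImageTile (PNG plus JSON metadata sidecar)
#'
#' @param tile an [ImageTile-class].
#' @param path PNG path; metadata goes to `<path>.json`.
#' @export
writeTile <- function(tile, path) {
  writeImagePNG(tile@array, path)
  jsonlite::write_json(list(case_id = tile@caseId, tile_id = tile@tileId,
                            origin = tile@origin,
                            microns_per_pixel = tile@micronsPerPixel),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTile
#' @export
readTile <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  imageTile(readImagePNG(path), caseId = meta$case_id, tileId = meta$tile_id,
            origin = meta$origin, micronsPerPixel = meta$microns_per_pixel)
}

#' Write / read a FeatureMap (indexed PNG plus JSON palette)
#'
#' The class-index raster is stored as a grayscale PNG (index / 255); the
#' classes, palette, scale and physical pixel size go to a JSON sidecar.
#'
#' @param featureMap a [FeatureMap-class].
#' @param path PNG path; the sidecar is `<path>.json`.
#' @export
writeFeatureMap <- function(featureMap, path) {
  png::writePNG(featureMap@raster / 255, path)
  jsonlite::write_json(list(classes = featureMap@classes,
                            palette = as.data.frame(featureMap@palette),
                            scale = featureMap@scale,
                            microns_per_pixel = featureMap@micronsPerPixel),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname writeFeatureMap
#' @export
readFeatureMap <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  raster <- round(png::readPNG(path) * 255)
  storage.mode(raster) <- "integer"
  new("FeatureMap", raster = raster, classes = meta$classes,
      palette = as.matrix(meta$palette), scale = meta$scale,
      micronsPerPixel = meta$microns_per_pixel)
}
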