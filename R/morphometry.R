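# Segmentation and measurement of discriminable cells: binarization at the
# Otsu statistic, outer-contour tracing of the largest component, and
# area / perimeter / compactness / minimum-intensity morphometry.

#' Binarize a signal patch at a threshold
#'
#' Foreground (`TRUE`, the cell) is `signal > sigma`, i.e. the cell of
#' interest in white on a black background. Idempotent on 0/1 masks for any
#' threshold strictly inside (0, 1).
#'
#' @param signal numeric matrix in `[0, 1]`.
#' @param sigma threshold in `[0, 1]` (typically the patch's Otsu statistic).
#' @return logical matrix.
#' @export
binarizeSignal <- function(signal, sigma) {
  if (sigma < 0 || sigma > 1) stop("sigma must lie in [0, 1]")
  signal > sigma
}

largestComponent <- function(mask) {
  lab <- cc_label_cpp(mask, 8L)
  if (max(lab) == 0L) return(NULL)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# Moore-neighbour boundary tracing. Returns the ordered closed outer
# boundary of the TRUE region as 0-based (x, y) points. Terminates when the
# (pixel, backtrack-direction) state of the first move recurs, so pinched
# boundaries are handled.
mooreTrace <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  inside <- function(y, x) y >= 1L && y <= H && x >= 1L && x <= W && mask[y, x]
  # start: topmost then leftmost foreground pixel (scanning row by row)
  start <- NULL
  for (y in seq_len(H)) {
    xs <- which(mask[y, ])
    if (length(xs)) { start <- c(y, xs[1]); break }
  }
  if (is.null(start)) return(NULL)
  # clockwise neighbour ring starting at west
  dy <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dx <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  pts <- list()
  cur <- start
  b <- 1L  # backtrack direction (scan starts just past it); west at start
  firstState <- NULL
  repeat {
    pts[[length(pts) + 1L]] <- c(cur[2] - 1L, cur[1] - 1L)  # (x, y), 0-based
    found <- FALSE
    for (step in 1:8) {
      k <- (b + step - 1L) %% 8L + 1L
      ny <- cur[1] + dy[k]; nx <- cur[2] + dx[k]
      if (inside(ny, nx)) {
        # new backtrack: direction from the new pixel to the neighbour
        # checked just before it (a background pixel)
        kprev <- (b + step - 2L) %% 8L + 1L
        bdy <- cur[1] + dy[kprev] - ny
        bdx <- cur[2] + dx[kprev] - nx
        b <- which(dy == bdy & dx == bdx)
        cur <- c(ny, nx)
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    state <- c(cur, b)
    if (is.null(firstState)) firstState <- state
    else if (all(state == firstState)) break
    if (length(pts) > 4L * H * W) stop("contour tracing failed to terminate")
  }
  pts <- do.call(rbind, pts)
  if (nrow(pts) > 1L && all(pts[nrow(pts), ] == pts[1L, ]))
    pts <- pts[-nrow(pts), , drop = FALSE]
  pts
}

#' Extract the closed outer contour of the cell in a mask
#'
#' Selects the largest 8-connected foreground component (the detected cell
#' dominates its centred crop) and traces its outer boundary with
#' Moore-neighbour tracing. Components smaller than `minArea` pixels are
#' rejected as unsegmentable debris.
#'
#' @param mask logical matrix (from [binarizeSignal()]).
#' @param minArea minimum component pixel count.
#' @return integer matrix of ordered 0-based `(x, y)` boundary points.
#' @export
extractCellContour <- function(mask, minArea = 5L) {
  if (!any(mask)) stop("no segmentable cell: the mask is empty")
  comp <- largestComponent(mask)
  if (sum(comp) < minArea)
    stop(sprintf("no segmentable cell: largest component has %d px (< %d)",
                 sum(comp), minArea))
  pts <- mooreTrace(comp)
  colnames(pts) <- c("x", "y")
  pts
}

#' Remove collinear points from a closed contour
#'
#' @param contour ordered point matrix from [extractCellContour()].
#' @return the simplified contour (vertices only).
#' @export
simplifyContour <- function(contour) {
  n <- nrow(contour)
  if (n < 3L) return(contour)
  keep <- logical(n)
  for (i in seq_len(n)) {
    p <- contour[(i - 2L) %% n + 1L, ]
    q <- contour[i, ]
    r <- contour[i %% n + 1L, ]
    keep[i] <- (q[1] - p[1]) * (r[2] - p[2]) -
      (q[2] - p[2]) * (r[1] - p[1]) != 0
  }
  contour[keep, , drop = FALSE]
}

chainPerimeter <- function(contour) {
  n <- nrow(contour)
  if (n < 2L) return(0)
  nxt <- rbind(contour[-1, , drop = FALSE], contour[1, , drop = FALSE])
  sum(sqrt(rowSums((nxt - contour)^2)))
}

# Pixels enclosed by the outer boundary of the largest component: component
# pixels plus any holes it surrounds (a halo ring's area includes its lumen).
enclosedArea <- function(mask) {
  comp <- largestComponent(mask)
  H <- nrow(comp); W <- ncol(comp)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- comp
  outside <- cc_label_cpp(!pad, 4L)
  borderLabs <- unique(c(outside[1, ], outside[H + 2L, ],
                         outside[, 1], outside[, W + 2L]))
  reach <- matrix(outside %in% borderLabs[borderLabs > 0L], H + 2L, W + 2L)
  inner <- reach[2:(H + 1L), 2:(W + 1L)]
  sum(comp | !inner)
}

#' Measure a segmented cell
#'
#' Area is the number of pixels enclosed by the cell's outer contour
#' (including any interior lumen of a ring-shaped cell). Perimeter is the
#' weighted chain length of the boundary (1 per axial step, sqrt(2) per
#' diagonal step); a plain boundary-pixel count is available via
#' `perimeterRule = "count"`. Compactness is `perimeter^2 / (4 * pi * area)`
#' (1 for a perfect disc). The minimum pixel intensity of the cell is
#' reported as the patch's Otsu statistic `sigma` — the intensity level
#' separating cell from background.
#'
#' @param mask logical matrix containing the cell.
#' @param sigma the patch's Otsu statistic (recorded as `min_intensity`).
#' @param minArea minimum component size, see [extractCellContour()].
#' @param perimeterRule `"chain"` (weighted, default) or `"count"`.
#' @return list with `area`, `perimeter`, `compactness`, `min_intensity`
#'   and the ordered `contour`.
#' @export
measureCell <- function(mask, sigma = NA_real_, minArea = 5L,
                        perimeterRule = c("chain", "count")) {
  perimeterRule <- match.arg(perimeterRule)
  contour <- extractCellContour(mask, minArea = minArea)
  area <- enclosedArea(mask)
  if (area <= 0) stop("zero-area contour")
  perimeter <- if (perimeterRule == "chain") chainPerimeter(contour)
               else nrow(unique(contour))
  list(area = area, perimeter = perimeter,
       compactness = perimeter^2 / (4 * pi * area),
       min_intensity = sigma, contour = contour)
}

#' Measure all discriminable detections of a case
#'
#' Re-derives each discriminable detection's signal patch, binarizes it at
#' the detection's own Otsu statistic and measures the segmented cell.
#' Detections whose mask has no segmentable component are dropped with a
#' message.
#'
#' @param tiles list of [ImageTile-class] objects.
#' @param detections data.frame from [filterDetections()] (needs `sigma` and
#'   `discriminable` columns).
#' @param gaussianSigma,enhance preprocessing settings (must match those used
#'   for the sigma computation).
#' @param window crop edge (default 64).
#' @param minArea see [extractCellContour()].
#' @return data.frame with one row per measured cell: provenance, centre,
#'   `area_px`, `perimeter_px`, `compactness`, `min_intensity`.
#' @export
measureDetections <- function(tiles, detections, gaussianSigma = 1,
                              enhance = TRUE, window = 64L, minArea = 5L) {
  key <- vapply(tiles, function(t) paste(t@caseId, t@tileId, sep = "\r"), "")
  names(tiles) <- key
  det <- detections[detections$discriminable, , drop = FALSE]
  rows <- list()
  dropped <- 0L
  half <- window %/% 2L
  for (i in seq_len(nrow(det))) {
    tile <- tiles[[paste(det$case_id[i], det$tile_id[i], sep = "\r")]]
    d <- dim(tile@array)
    x <- min(max(det$x[i], half), d[2] - half)
    y <- min(max(det$y[i], half), d[1] - half)
    crop <- tile@array[(y - half + 1):(y + half), (x - half + 1):(x + half), ,
                       drop = FALSE]
    signal <- preprocessPatch(crop, gaussianSigma, enhance)
    m <- tryCatch(
      measureCell(binarizeSignal(signal, det$sigma[i]), sigma = det$sigma[i],
                  minArea = minArea),
      error = function(e) NULL)
    if (is.null(m)) { dropped <- dropped + 1L; next }
    rows[[length(rows) + 1L]] <-
      data.frame(case_id = det$case_id[i], tile_id = det$tile_id[i],
                 x = det$x[i], y = det$y[i], area_px = m$area,
                 perimeter_px = m$perimeter, compactness = m$compactness,
                 min_intensity = m$min_intensity, stringsAsFactors = FALSE)
  }
  if (dropped > 0L) message(dropped, " detection(s) had no segmentable cell")
  if (!length(rows))
    return(data.frame(case_id = character(0), tile_id = character(0),
                      x = integer(0), y = integer(0), area_px = numeric(0),
                      perimeter_px = numeric(0), compactness = numeric(0),
                      min_intensity = numeric(0)))
  do.call(rbind, rows)
}

#' Case-level mean morphometry and cell density
#'
#' Arithmetic means of area, perimeter, compactness and minimum intensity
#' over a case's measured cells, plus the cell density per square
#' millimetre of tissue.
#'
#' @param cells data.frame from [measureDetections()].
#' @param tissueAreaMm2 tissue area in mm^2 (e.g. tile pixel count times
#'   `mpp^2 / 1e6`).
#' @return one-row data.frame: `n_cells`, `mean_area_px`,
#'   `mean_perimeter_px`, `mean_compactness`, `mean_min_intensity`,
#'   `density_per_mm2`.
#' @export
caseSummary <- function(cells, tissueAreaMm2) {
  if (tissueAreaMm2 <= 0) stop("tissueAreaMm2 must be positive")
  n <- nrow(cells)
  if (n == 0L)
    return(data.frame(n_cells = 0L, mean_area_px = NA_real_,
                      mean_perimeter_px = NA_real_,
                      mean_compactness = NA_real_,
                      mean_min_intensity = NA_real_, density_per_mm2 = 0))
  data.frame(n_cells = n, mean_area_px = mean(cells$area_px),
             mean_perimeter_px = mean(cells$perimeter_px),
             mean_compactness = mean(cells$compactness),
             mean_min_intensity = mean(cells$min_intensity),
             density_per_mm2 = n / tissueAreaMm2)
}
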