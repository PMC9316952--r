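# Post-processing of detected cells: signal preprocessing, the per-patch
# Otsu statistic sigma, the per-case acceptance threshold
# T = mean(sigma) - min(sigma), and the discriminable / less-discriminable
# partition.

#' Preprocess a detection crop into a stain-signal patch
#'
#' Converts the RGB crop to an inverted grayscale stain signal in which the
#' immunoreactive ("halo") ring pixels carry the highest values, removes
#' noise with a Gaussian filter (each pixel replaced by a Gaussian-weighted
#' neighbourhood average), and optionally enhances local contrast so each
#' output pixel reflects the intensity variation in its neighbourhood (3x3
#' local range). Output is clipped to `[0, 1]`.
#'
#' The grayscale conversion is chromogen-selective: the inverted luminance
#' `1 - Y` is weighted by how brown (high red/green, low blue) each pixel is,
#' which suppresses the blue-grey counterstained nuclei. This mirrors the
#' stain-separation step of standard IHC image analysis; without it every
#' crop's Otsu statistic is dominated by counterstain nucleus edges and no
#' longer reflects chromogen strength. Pass `chromogenOnly = FALSE` for the
#' plain inverted luminance.
#'
#' @param crop `(H, W, 3)` RGB array, or an already-grayscale matrix (taken
#'   as luminance and inverted).
#' @param gaussianSigma smoothing s.d. in pixels; 0 disables smoothing.
#' @param enhance apply the local-contrast step.
#' @param chromogenOnly weight the signal by brown-ness (default).
#' @return numeric matrix in `[0, 1]`.
#' @export
preprocessPatch <- function(crop, gaussianSigma = 1, enhance = TRUE,
                            chromogenOnly = TRUE) {
  if (length(dim(crop)) == 3L) {
    signal <- 1 - luminance(crop)
    if (chromogenOnly) {
      brown <- (crop[, , 1] + crop[, , 2]) / 2 - crop[, , 3]
      signal <- signal * clip01(brown / 0.05)
    }
  } else {
    signal <- 1 - crop
  }
  signal <- gaussianBlur(signal, gaussianSigma)
  if (enhance) signal <- localRange(signal)
  clip01(signal)
}

#' Otsu statistic of a signal patch
#'
#' Histogram the signal into `bins` equal-width bins over `[0, 1]` and return
#' the bin-centre threshold that maximises the between-class variance
#' (equivalently, minimises the intra-class variance). Ties are broken by the
#' lowest qualifying threshold. A constant patch has no bimodal split and is
#' an error; callers treat that case as less-discriminable.
#'
#' @param signal numeric matrix (or vector) in `[0, 1]`.
#' @param bins histogram resolution.
#' @return the Otsu statistic sigma, a value in `[0, 1]`.
#' @export
otsuStatistic <- function(signal, bins = 256L) {
  v <- as.numeric(signal)
  if (length(v) < 2L || max(v) - min(v) < .Machine$double.eps)
    stop("constant signal: no foreground/background split exists")
  b <- pmin(as.integer(floor(v * bins)), bins - 1L)
  h <- tabulate(b + 1L, nbins = bins)
  p <- h / sum(h)
  centres <- (seq_len(bins) - 0.5) / bins
  w0 <- cumsum(p)
  m0 <- cumsum(p * centres)
  mu <- m0[bins]
  k <- seq_len(bins - 1L)
  valid <- w0[k] > 0 & w0[k] < 1
  bcv <- rep(-Inf, bins - 1L)
  bcv[valid] <- (mu * w0[k][valid] - m0[k][valid])^2 /
    (w0[k][valid] * (1 - w0[k][valid]))
  centres[which.max(bcv)]
}

#' Per-case acceptance threshold from the Otsu statistics
#'
#' The minimum acceptance value for the Otsu statistic of a case's
#' detections: `T = sum(sigma)/N - min(sigma)`, i.e. the mean statistic minus
#' the lowest statistic among the case's patches. Because antibody labelling
#' intensity differs between slides, `T` is computed per whole-slide image
#' (per case), never globally.
#'
#' @param sigmas numeric vector of per-patch Otsu statistics (at least one).
#' @return a [ThresholdSummary-class] carrying `sigma`, `N`, `sum(sigma)`,
#'   `min(sigma)` and `T`.
#' @export
acceptanceThreshold <- function(sigmas) {
  sigmas <- as.numeric(sigmas)
  if (length(sigmas) < 1L || anyNA(sigmas))
    stop("at least one finite sigma value is required")
  new("ThresholdSummary", sigma = sigmas, n = length(sigmas),
      sigmaSum = sum(sigmas), tMin = min(sigmas),
      T = sum(sigmas) / length(sigmas) - min(sigmas))
}

#' Partition detections into discriminable and less-discriminable cells
#'
#' A detection is discriminable when its Otsu statistic surpasses the
#' acceptance threshold: `sigma > T` (strict by default; `strict = FALSE`
#' uses `>=`). Records with missing sigma (constant patches) are always
#' less-discriminable. The two outputs partition the input.
#'
#' @param records data.frame of detections with a `sigma` column.
#' @param summary a [ThresholdSummary-class] computed from these records'
#'   case.
#' @param strict use strict comparison.
#' @return `list(discriminable = , lessDiscriminable = )` data.frames.
#' @export
partitionDetections <- function(records, summary, strict = TRUE) {
  if (!"sigma" %in% names(records)) stop("records need a 'sigma' column")
  keep <- if (strict) records$sigma > summary@T else records$sigma >= summary@T
  keep[is.na(keep)] <- FALSE
  list(discriminable = records[keep, , drop = FALSE],
       lessDiscriminable = records[!keep, , drop = FALSE])
}

#' Compute sigma, T and the discriminable flag for detections
#'
#' Convenience chain over whole cases: extracts the wide crop around every
#' detection, preprocesses it, computes the Otsu statistic, derives the
#' per-case acceptance threshold and flags each detection. Constant crops
#' yield `sigma = NA` and are less-discriminable.
#'
#' @param tiles list of [ImageTile-class] objects covering the detections.
#' @param detections data.frame from [mergeDetections()] (possibly several
#'   tiles/cases bound together).
#' @param gaussianSigma,enhance see [preprocessPatch()].
#' @param strict see [partitionDetections()].
#' @param window crop edge around each detection (default 64).
#' @return `list(detections = , summaries = )`: the input with `sigma`,
#'   `threshold_T` and `discriminable` columns added, plus one
#'   [ThresholdSummary-class] per case.
#' @export
filterDetections <- function(tiles, detections, gaussianSigma = 1,
                             enhance = TRUE, strict = TRUE, window = 64L) {
  key <- vapply(tiles, function(t) paste(t@caseId, t@tileId, sep = "\r"), "")
  names(tiles) <- key
  n <- nrow(detections)
  sig <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tile <- tiles[[paste(detections$case_id[i], detections$tile_id[i],
                         sep = "\r")]]
    if (is.null(tile)) stop("detection references unknown tile ",
                            detections$tile_id[i])
    d <- dim(tile@array)
    half <- window %/% 2L
    x <- min(max(detections$x[i], half), d[2] - half)
    y <- min(max(detections$y[i], half), d[1] - half)
    crop <- tile@array[(y - half + 1):(y + half), (x - half + 1):(x + half), ,
                       drop = FALSE]
    signal <- preprocessPatch(crop, gaussianSigma, enhance)
    sig[i] <- tryCatch(otsuStatistic(signal), error = function(e) NA_real_)
  }
  detections$sigma <- sig
  detections$threshold_T <- rep(NA_real_, n)
  detections$discriminable <- rep(FALSE, n)
  summaries <- list()
  for (cs in unique(detections$case_id)) {
    sel <- detections$case_id == cs & !is.na(detections$sigma)
    if (!any(sel)) next
    sm <- acceptanceThreshold(detections$sigma[sel])
    summaries[[cs]] <- sm
    csel <- detections$case_id == cs
    detections$threshold_T[csel] <- sm@T
    keep <- if (strict) detections$sigma[csel] > sm@T
            else detections$sigma[csel] >= sm@T
    keep[is.na(keep)] <- FALSE
    detections$discriminable[csel] <- keep
  }
  list(detections = detections, summaries = summaries)
}

#' Export a threshold summary as JSON
#'
#' @param summary a [ThresholdSummary-class].
#' @param path output path.
#' @export
writeThresholdSummary <- function(summary, path) {
  jsonlite::write_json(list(n = summary@n, sigma_sum = summary@sigmaSum,
                            t_min = summary@tMin, T = summary@T),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
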