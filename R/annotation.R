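# Mark-point I/O and bifocal patch-pair dataset construction.

markColumns <- c("case_id", "tile_id", "x", "y", "label")

#' Read mark-point annotations from CSV
#'
#' Expects the header `case_id,tile_id,x,y,label` (optionally followed by
#' `intensity` and `stratum` columns emitted by the synthetic generator).
#' Coordinates are 0-based integers with `x` the column and `y` the row.
#' Malformed rows are rejected with their row number.
#'
#' @param path CSV file path.
#' @return data.frame of mark points.
#' @export
readMarks <- function(path) {
  dt <- data.table::fread(path, data.table = FALSE)
  missing <- setdiff(markColumns, names(dt))
  if (length(missing))
    stop("missing columns in ", path, ": ", paste(missing, collapse = ", "))
  for (cc in c("case_id", "tile_id", "label")) dt[[cc]] <- as.character(dt[[cc]])
  bad <- which(!is.finite(dt$x) | !is.finite(dt$y) |
                 dt$x != floor(dt$x) | dt$y != floor(dt$y))
  if (length(bad))
    stop("non-integer or missing coordinates at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(dt$x < 0 | dt$y < 0)
  if (length(bad))
    stop("negative coordinates at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!dt$label %in% c("positive", "negative"))
  if (length(bad))
    stop("unknown label at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  dt$x <- as.integer(dt$x)
  dt$y <- as.integer(dt$y)
  dt
}

#' Write mark-point annotations to CSV
#'
#' @param marks data.frame with at least the columns
#'   `case_id,tile_id,x,y,label`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeMarks <- function(marks, path) {
  missing <- setdiff(markColumns, names(marks))
  if (length(missing))
    stop("marks is missing columns: ", paste(missing, collapse = ", "))
  keep <- c(markColumns, intersect(c("intensity", "stratum"), names(marks)))
  data.table::fwrite(marks[, keep, drop = FALSE], path)
  invisible(path)
}

#' Extract one co-centred bifocal patch pair
#'
#' Crops the narrow (`size` x `size`) and wide (`2*size` x `2*size`) windows
#' centred on `centre` using half-open ranges `[c - s/2, c + s/2)`, so the
#' narrow crop is exactly the central sub-window of the wide crop. Centres
#' closer than `size` pixels to a border are an error: no padding is done,
#' because fabricated context would defeat the bifocal design.
#'
#' @param tile an [ImageTile-class].
#' @param centre 0-based `(x, y)` centre.
#' @param size narrow patch edge in pixels (default 32).
#' @param label optional `"positive"`/`"negative"` label.
#' @return a [BifocalPatchSet-class] of length 1.
#' @export
extractBifocalPair <- function(tile, centre, size = 32L, label = NA) {
  d <- dim(tile@array)
  H <- d[1]; W <- d[2]
  x <- centre[1]; y <- centre[2]
  s <- as.integer(size)
  if (x < s || x > W - s || y < s || y > H - s)
    stop(sprintf(paste0("centre (%d, %d) is closer than %d px to a border of ",
                        "the %d x %d tile; both focal crops must fit"),
                 x, y, s, W, H))
  narrow <- tile@array[(y - s / 2 + 1):(y + s / 2), (x - s / 2 + 1):(x + s / 2), ,
                       drop = FALSE]
  wide <- tile@array[(y - s + 1):(y + s), (x - s + 1):(x + s), , drop = FALSE]
  new("BifocalPatchSet",
      narrow = array(narrow, dim = c(s, s, 3, 1)),
      wide = array(wide, dim = c(2 * s, 2 * s, 3, 1)),
      labels = factor(label, levels = c("negative", "positive")),
      centres = matrix(c(x, y), 1, 2, dimnames = list(NULL, c("x", "y"))),
      caseIds = tile@caseId, tileIds = tile@tileId)
}

# Stack many crops from one tile quickly (no per-pair S4 objects).
extractCrops <- function(tileArr, centres, size) {
  s <- as.integer(size)
  n <- nrow(centres)
  out <- array(0, dim = c(s, s, 3, n))
  for (i in seq_len(n)) {
    x <- centres[i, 1]; y <- centres[i, 2]
    out[, , , i] <- tileArr[(y - s / 2 + 1):(y + s / 2),
                            (x - s / 2 + 1):(x + s / 2), , drop = FALSE]
  }
  out
}

applyAugment <- function(img, rot, contrast, sharp) {
  img <- rotate90(img, rot)
  img <- clip01((img - 0.5) * contrast + 0.5)
  if (sharp != 1) {
    blur <- img
    for (ch in 1:3) blur[, , ch] <- gaussianBlur(img[, , ch], 1)
    img <- clip01(blur + sharp * (img - blur))
  }
  img
}

#' Build a labelled bifocal training set from tiles and marks
#'
#' One patch pair per mark point; marks whose crops would cross a tile border
#' are skipped with a message (no padding). With `augment = TRUE`, each pair
#' is additionally emitted `variants` times under a random right-angle
#' rotation, contrast and sharpness scaling drawn from `[0.8, 1.2]`, and a
#' small random translation of the crop centre (up to `jitter` pixels per
#' axis, clamped to the tile interior) emulating the overlapping stride
#' extraction that sliding-window inference sees; the same photometric
#' transform is applied to both crops. Augmentation is seed-deterministic.
#'
#' @param tiles list of [ImageTile-class] objects covering the marks.
#' @param marks data.frame as returned by [readMarks()].
#' @param augment emit augmented variants as well.
#' @param variants number of augmented variants per mark.
#' @param jitter maximum augmentation translation per axis, in pixels.
#' @param seed seed for the augmentation draws.
#' @param size narrow patch edge (default 32).
#' @return a [BifocalPatchSet-class].
#' @export
buildTrainingSet <- function(tiles, marks, augment = FALSE, variants = 3L,
                             jitter = 5L, seed = 1L, size = 32L) {
  key <- vapply(tiles, function(t) paste(t@caseId, t@tileId, sep = "\r"), "")
  names(tiles) <- key
  s <- as.integer(size)
  mk <- paste(marks$case_id, marks$tile_id, sep = "\r")
  unknown <- !mk %in% key
  if (any(unknown))
    stop("marks reference unknown tiles: ",
         paste(unique(paste(marks$case_id[unknown], marks$tile_id[unknown])),
               collapse = ", "))
  # border-mark filter
  ok <- logical(nrow(marks))
  for (i in seq_len(nrow(marks))) {
    d <- dim(tiles[[mk[i]]]@array)
    ok[i] <- marks$x[i] >= s && marks$x[i] <= d[2] - s &&
      marks$y[i] >= s && marks$y[i] <= d[1] - s
  }
  if (any(!ok))
    message(sum(!ok), " border mark(s) skipped (crops would cross the tile edge)")
  marks <- marks[ok, , drop = FALSE]
  mk <- mk[ok]
  n <- nrow(marks)
  if (n == 0L) stop("no usable marks")

  reps <- if (augment) 1L + as.integer(variants) else 1L
  narrow <- array(0, dim = c(s, s, 3, n * reps))
  wide <- array(0, dim = c(2 * s, 2 * s, 3, n * reps))
  withSeed(seed, {
    for (i in seq_len(n)) {
      arr <- tiles[[mk[i]]]@array
      x <- marks$x[i]; y <- marks$y[i]
      nr <- arr[(y - s / 2 + 1):(y + s / 2), (x - s / 2 + 1):(x + s / 2), ,
                drop = FALSE]
      wd <- arr[(y - s + 1):(y + s), (x - s + 1):(x + s), , drop = FALSE]
      narrow[, , , i] <- nr
      wide[, , , i] <- wd
      if (reps > 1L) {
        d <- dim(arr)
        for (v in seq_len(reps - 1L)) {
          rot <- sample.int(4L, 1) - 1L
          ctr <- stats::runif(1, 0.8, 1.2)
          shp <- stats::runif(1, 0.8, 1.2)
          jx <- sample(seq(-jitter, jitter), 1)
          jy <- sample(seq(-jitter, jitter), 1)
          cx <- min(max(x + jx, s), d[2] - s)
          cy <- min(max(y + jy, s), d[1] - s)
          nrj <- arr[(cy - s / 2 + 1):(cy + s / 2),
                     (cx - s / 2 + 1):(cx + s / 2), , drop = FALSE]
          wdj <- arr[(cy - s + 1):(cy + s), (cx - s + 1):(cx + s), ,
                     drop = FALSE]
          narrow[, , , n * v + i] <- applyAugment(nrj, rot, ctr, shp)
          wide[, , , n * v + i] <- applyAugment(wdj, rot, ctr, shp)
        }
      }
    }
  })
  lab <- factor(rep(marks$label, reps), levels = c("negative", "positive"))
  new("BifocalPatchSet", narrow = narrow, wide = wide, labels = lab,
      centres = cbind(x = rep(marks$x, reps), y = rep(marks$y, reps)),
      caseIds = rep(marks$case_id, reps), tileIds = rep(marks$tile_id, reps))
}

#' Split marks into train and test sets by case, enforcing disjointness
#'
#' Training and testing data must come from different cases; any overlap
#' between the declared case sets is an error.
#'
#' @param marks data.frame of mark points.
#' @param trainCases,testCases character vectors of case ids.
#' @return `list(train = , test = )` data.frames.
#' @export
splitMarksByCase <- function(marks, trainCases, testCases) {
  overlap <- intersect(trainCases, testCases)
  if (length(overlap))
    stop("train and test case sets overlap: ", paste(overlap, collapse = ", "))
  list(train = marks[marks$case_id %in% trainCases, , drop = FALSE],
       test = marks[marks$case_id %in% testCases, , drop = FALSE])
}

#' Enumerate sliding-window inference centres over a tile
#'
#' Centres form a regular lattice such that every wide (`window` x `window`)
#' crop lies inside the tile: per axis there are
#' `floor((dim - window) / stride) + 1` centres starting at `window / 2`,
#' ordered row-major from the upper left to the bottom right.
#'
#' @param tile an [ImageTile-class], or a numeric `(width, height)` pair.
#' @param stride lattice spacing in pixels (default 10).
#' @param window wide crop edge in pixels (default 64).
#' @return integer matrix with columns `x`, `y` (0-based centres).
#' @export
enumerateInferenceCentres <- function(tile, stride = 10L, window = 64L) {
  if (is(tile, "ImageTile")) {
    d <- dim(tile@array); W <- d[2]; H <- d[1]
  } else {
    W <- tile[1]; H <- tile[2]
  }
  if (W < window || H < window)
    stop(sprintf("tile (%d x %d) is smaller than the %d px window", W, H,
                 window))
  half <- window %/% 2L
  xs <- half + stride * (0:((W - window) %/% stride))
  ys <- half + stride * (0:((H - window) %/% stride))
  cbind(x = as.integer(rep(xs, times = length(ys))),
        y = as.integer(rep(ys, each = length(xs))))
}
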