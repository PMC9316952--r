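# Shared fixtures: tiny synthetic configs, a memoised tiny trained model,
# and independent oracles used across test files.

tinySynth <- function(tileWidth = 160L, tileHeight = 160L, nCells = 4L,
                      nNegatives = 4L, nucleiDensity = 25L, seed = 5L, ...) {
  syntheticConfig(tileWidth = tileWidth, tileHeight = tileHeight,
                  nCells = nCells, nNegatives = nNegatives,
                  nucleiDensity = nucleiDensity, seed = seed, ...)
}

twoStrata <- function() {
  list(list(name = "weak", range = c(0.2, 0.35), weight = 0.5),
       list(name = "strong", range = c(0.6, 0.9), weight = 0.5))
}

tinyBcnnConfig <- function(seed = 7L) {
  bcnnConfig(channels = c(3L, 4L, 6L), hidden = 8L, seed = seed)
}

# One small trained model per test run, trained lazily on a small two-tile
# case; enough to separate rings from background.
.modelCache <- new.env(parent = emptyenv())
tinyTrainedModel <- function() {
  if (!is.null(.modelCache$model)) return(.modelCache$model)
  cfg <- syntheticConfig(tileWidth = 256L, tileHeight = 256L, nCells = 10L,
                         nNegatives = 10L, nucleiDensity = 60L,
                         intensityStrata = twoStrata(), seed = 41L)
  cs <- generateCase(cfg, nTiles = 2, caseId = "helper")
  pairs <- buildTrainingSet(cs$tiles, cs$marks, augment = TRUE,
                            variants = 1L, seed = 8L)
  model <- buildModel(bcnnConfig(channels = c(6L, 10L, 14L), hidden = 16L,
                                 seed = 9L))
  .modelCache$model <- trainModel(model, pairs, epochs = 8)
  .modelCache$model
}

# Brute-force Otsu oracle: quantize to bin centres, then try every split and
# compute the between-class variance from the raw class members.
bruteOtsu <- function(signal, bins = 256L) {
  v <- as.numeric(signal)
  centres <- (seq_len(bins) - 0.5) / bins
  q <- centres[pmin(floor(v * bins), bins - 1L) + 1L]
  best <- -Inf
  bestT <- NA_real_
  for (k in seq_len(bins - 1L)) {
    t <- centres[k]
    lo <- q[q <= t]; hi <- q[q > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(q)
    bcv <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (bcv > best + 1e-15) { best <- bcv; bestT <- t }
  }
  bestT
}

# Exhaustive sliding-window centre enumeration (independent of the
# closed-form lattice).
bruteCentres <- function(W, H, stride = 10L, window = 64L) {
  out <- NULL
  y <- window / 2
  while (y + window / 2 <= H) {
    x <- window / 2
    while (x + window / 2 <= W) {
      out <- rbind(out, c(x, y))
      x <- x + stride
    }
    y <- y + stride
  }
  out
}

# A filled random blob (union of two overlapping discs), simply connected.
randomBlobMask <- function(H = 60L, W = 60L) {
  cx1 <- runif(1, 20, W - 20); cy1 <- runif(1, 20, H - 20)
  r1 <- runif(1, 6, 12); r2 <- runif(1, 5, 10)
  ang <- runif(1, 0, 2 * pi); d <- runif(1, 0, r1)
  cx2 <- cx1 + d * cos(ang); cy2 <- cy1 + d * sin(ang)
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), W), H, W)
  (xs - cx1)^2 + (ys - cy1)^2 <= r1^2 | (xs - cx2)^2 + (ys - cy2)^2 <= r2^2
}

gridFromMatrix <- function(m, stride = 10L) {
  new("HeatmapGrid", scores = m, stride = stride, originOffset = 32L,
      caseId = "c", tileId = "t", tileOrigin = c(0, 0),
      micronsPerPixel = 0.25)
}

discMask <- function(r, pad = 4L) {
  n <- 2L * (r + pad) + 1L
  c0 <- r + pad + 1L
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  ys <- matrix(rep(seq_len(n), n), n, n)
  (xs - c0)^2 + (ys - c0)^2 <= r^2
}
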