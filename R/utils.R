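# Internal helpers: seeded evaluation, image arithmetic, smoothing.

# Evaluate `expr` under `seed` and restore the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministically derive a sub-seed below 2^31 from a base seed and index.
deriveSeed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483647)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Relative luminance (Rec. 709 weights) of an (H, W, 3) array in [0, 1].
luminance <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
}

# One-dimensional Gaussian smoothing matrix (n x n), truncated at 3*sigma and
# row-renormalised so borders keep unit mass.
gaussianBandMatrix <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  i <- seq_len(n)
  K <- outer(i, i, function(a, b) {
    d <- a - b
    ifelse(abs(d) <= r, exp(-d^2 / (2 * sigma^2)), 0)
  })
  K / rowSums(K)
}

# Separable Gaussian blur of a matrix; sigma = 0 is the identity.
gaussianBlur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  Kr <- gaussianBandMatrix(nrow(x), sigma)
  Kc <- gaussianBandMatrix(ncol(x), sigma)
  Kr %*% x %*% t(Kc)
}

# Shift a matrix by (dy, dx) with edge replication.
shiftReplicate <- function(x, dy, dx) {
  H <- nrow(x); W <- ncol(x)
  ri <- pmin(pmax(seq_len(H) + dy, 1L), H)
  ci <- pmin(pmax(seq_len(W) + dx, 1L), W)
  x[ri, ci, drop = FALSE]
}

# Local contrast (max - min over the 3x3 neighbourhood, edges replicated).
localRange <- function(x) {
  mx <- x
  mn <- x
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    s <- shiftReplicate(x, dy, dx)
    mx <- pmax(mx, s)
    mn <- pmin(mn, s)
  }
  mx - mn
}

# Rotate an (H, W, 3) array counter-clockwise by k * 90 degrees.
rotate90 <- function(img, k) {
  k <- k %% 4L
  if (k == 0L) return(img)
  for (i in seq_len(k)) {
    H <- dim(img)[1]; W <- dim(img)[2]
    out <- array(0, dim = c(W, H, 3))
    for (ch in 1:3) out[, , ch] <- t(img[, , ch])[W:1, , drop = FALSE]
    img <- out
  }
  img
}

md5OfFile <- function(path) unname(tools::md5sum(path))
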