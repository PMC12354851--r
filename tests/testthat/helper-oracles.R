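# Independent brute-force oracles used to validate the package's fast paths.
# These deliberately share no code with the implementation.

# O(N^2) 2D histogram by explicit per-event loop.
oracle_histogram2d <- function(x, y, spacing, nx, ny, origin = c(0, 0)) {
  h <- matrix(0L, nx, ny)
  for (i in seq_along(x)) {
    ix <- floor((x[i] - origin[1]) / spacing) + 1
    iy <- floor((y[i] - origin[2]) / spacing) + 1
    if (ix >= 1 && ix <= nx && iy >= 1 && iy <= ny)
      h[ix, iy] <- h[ix, iy] + 1L
  }
  h
}

# Exhaustive nearest-foreground Euclidean distance.
oracle_distance_map <- function(mask, spacing = 1) {
  fg <- which(mask, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    out[i, j] <- sqrt(min((fg[, 1] - i)^2 + (fg[, 2] - j)^2)) * spacing
  }
  out
}

# Exhaustive Otsu: try all 256 candidate thresholds, maximize between-class
# variance.
oracle_otsu <- function(img, levels = 256) {
  lo <- min(img); hi <- max(img)
  v <- (as.vector(img) - lo) / (hi - lo)
  cand <- (seq_len(levels - 1)) / levels
  best <- cand[1]; bestvar <- -Inf
  for (t in cand) {
    a <- v[v <= t]; b <- v[v > t]
    if (!length(a) || !length(b)) next
    w <- length(a) / length(v)
    bc <- w * (1 - w) * (mean(a) - mean(b))^2
    if (bc > bestvar) { bestvar <- bc; best <- t }
  }
  best * (hi - lo) + lo
}

# Quadrature decay weight: integral of lambda * exp(-lambda t) over windows.
oracle_decay_weight <- function(windows, lambda) {
  s <- 0
  for (i in seq_len(nrow(windows)))
    s <- s + stats::integrate(function(t) lambda * exp(-lambda * t),
                              windows[i, 1], windows[i, 2])$value
  s
}

# A small standard dot phantom shared by warp tests.
test_dot_spec <- function(rows = 6, cols = 8)
  phantom_spec("dots", element_size = 160, spacing = 420,
               grid_rows = rows, grid_cols = cols,
               image_shape = c(160, 130), pixel_spacing = 26.5)

# Index matrix of the nearest pixel to each physical point (x, y in um).
px_index <- function(pts, spacing, shape)
  cbind(pmin(pmax(round(pts[, 1] / spacing + 0.5), 1), shape[1]),
        pmin(pmax(round(pts[, 2] / spacing + 0.5), 1), shape[2]))

# Between-class variance of a threshold on raw data (for comparing Otsu
# implementations whose argmax may be tied across an empty histogram gap).
between_class_variance <- function(img, thr) {
  v <- as.vector(img)
  a <- v[v <= thr]; b <- v[v > thr]
  if (!length(a) || !length(b)) return(0)
  w <- length(a) / length(v)
  w * (1 - w) * (mean(a) - mean(b))^2
}
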