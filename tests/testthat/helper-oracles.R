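# Independent oracles used across the suite. These deliberately avoid the
# package's own geometry/filtering internals.

# Distance from every pixel center (0-based) to a densely sampled polyline
# approximating a centerline; brute-force, O(pixels x samples).
polyline_distance_oracle <- function(shape, pts) {
  nr <- shape[1]; nc <- shape[2]
  d <- matrix(Inf, nr, nc)
  X <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  Y <- matrix(rep(seq_len(nr) - 1, times = nc), nr, nc)
  for (i in seq_len(nrow(pts)))
    d <- pmin(d, sqrt((X - pts[i, 1])^2 + (Y - pts[i, 2])^2))
  d
}

# Exact distance from pixel centers to a straight segment (closed form).
segment_distance_oracle <- function(shape, p0, p1) {
  nr <- shape[1]; nc <- shape[2]
  X <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  Y <- matrix(rep(seq_len(nr) - 1, times = nc), nr, nc)
  vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
  len2 <- vx^2 + vy^2
  t <- pmin(pmax(((X - p0[1]) * vx + (Y - p0[2]) * vy) / len2, 0), 1)
  sqrt((X - (p0[1] + t * vx))^2 + (Y - (p0[2] + t * vy))^2)
}

# Direct spatial correlation of `image` with `kernel` at one pixel
# (1-based row/col), with symmetric boundary extension done by index
# reflection.
correlate_at_oracle <- function(image, kernel, row, col) {
  h <- (nrow(kernel) - 1L) / 2L
  nr <- nrow(image); nc <- ncol(image)
  reflect <- function(i, n) {
    # reflect 1-based indices into 1..n (symmetric, edge pixel duplicated)
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > n, 2L * n + 1L - i, i)
  }
  acc <- 0
  for (dy in -h:h) for (dx in -h:h)
    acc <- acc + kernel[dy + h + 1L, dx + h + 1L] *
      image[reflect(row + dy, nr), reflect(col + dx, nc)]
  acc
}

# Per-pixel sector classification by angle (half-open sectors), written
# independently of quadrant_masks().
sector_oracle <- function(shape, center) {
  nr <- shape[1]; nc <- shape[2]
  out <- matrix(NA_character_, nr, nc)
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    dx <- (cl - 1) - center[1]; dy <- (r - 1) - center[2]
    if (dx == 0 && dy == 0) { out[r, cl] <- "top"; next }
    ang <- atan2(dy, dx) * 180 / pi
    out[r, cl] <-
      if (ang >= -135 && ang < -45) "top"
      else if (ang >= -45 && ang < 45) "right"
      else if (ang >= 45 && ang < 135) "bottom"
      else "left"
  }
  out
}

# rotate a matrix 90 degrees clockwise
rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])

dice_coefficient <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Small straight-vessel phantom used by several tests.
straight_vessel_phantom <- function(grid = 100, width = 2, noise = 0) {
  cfg <- phantom_config(grid_size = grid, n_vessels = 0,
                        background_noise_sd = noise, seed = 5)
  ves <- data.frame(x0 = 10, y0 = grid / 2, phi = 0, k = 0,
                    width = width, length = grid - 20)
  generate_vessel_network(cfg, vessels = ves)
}
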