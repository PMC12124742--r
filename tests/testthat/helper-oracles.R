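# Independent brute-force oracles used across the test files.  These are
# deliberately written against the naive definitions (quadratic scans,
# numerical area integration) rather than the package's fast paths.

# all pairs with d < r_i + r_j via an O(N^2) scan (minimum-image on request)
brute_pairs <- function(cells, Lx = NULL, Ly = NULL, px = FALSE, py = FALSE) {
  n <- nrow(cells)
  out <- list()
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq.int(i + 1, n)) {
      dx <- cells$x[i] - cells$x[j]
      dy <- cells$y[i] - cells$y[j]
      if (px) dx <- dx - round(dx / Lx) * Lx
      if (py) dy <- dy - round(dy / Ly) * Ly
      d <- sqrt(dx^2 + dy^2)
      if (d < cells$r[i] + cells$r[j])
        out[[length(out) + 1]] <- c(i, j, d)
    }
  }
  if (length(out) == 0)
    return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  m <- do.call(rbind, out)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]), d = m[, 3])
}

brute_overlap_area <- function(cells, ...) {
  pr <- brute_pairs(cells, ...)
  if (nrow(pr) == 0) return(0)
  sum(lens_area(cells$r[pr$i], cells$r[pr$j], pr$d))
}

brute_overlap_ratio <- function(cells, ...) {
  if (nrow(cells) == 0) return(0)
  brute_overlap_area(cells, ...) / sum(pi * cells$r^2)
}

# area of the axis-aligned square footprint of a cell clipped to one grid
# unit, by midpoint quadrature on a fine subgrid (independent of the
# interval-intersection arithmetic used by the rasterizer)
quadrature_occupancy <- function(xc, yc, rx, ry, i, j, m = 400) {
  xs <- i + (seq_len(m) - 0.5) / m
  ys <- j + (seq_len(m) - 0.5) / m
  inx <- xs >= xc - rx & xs <= xc + rx
  iny <- ys >= yc - ry & ys <= yc + ry
  sum(outer(inx, iny)) / m^2
}

# Monte-Carlo estimate of the intersection area of two discs
mc_lens_area <- function(r1, r2, d, n = 2e5) {
  # sample inside the smaller disc, count points inside the other
  if (r1 > r2) { tmp <- r1; r1 <- r2; r2 <- tmp }
  th <- runif(n, 0, 2 * pi)
  rad <- r1 * sqrt(runif(n))
  x <- rad * cos(th)
  y <- rad * sin(th)
  mean((x - d)^2 + y^2 <= r2^2) * pi * r1^2
}

expect_cells_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$id, b$id)
  expect_equal(a$x, b$x, tolerance = tol)
  expect_equal(a$y, b$y, tolerance = tol)
  expect_equal(a$r, b$r, tolerance = tol)
  expect_equal(a$biomass, b$biomass, tolerance = tol)
}

# random occupancy matrix with a controlled fraction of over-occupied units
random_omega <- function(W, H, over_frac = 0.2, max_over = 1.5) {
  m <- matrix(runif(W * H, 0, 1), W, H)
  k <- round(over_frac * W * H)
  if (k > 0) {
    idx <- sample(W * H, k)
    m[idx] <- runif(k, 1, max_over)
  }
  m
}
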