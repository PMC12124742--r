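test_that("cell bounds follow the bounding-square formula", {
  g <- grid_spec(20, 20)
  b <- compute_cell_bounds(5.5, 5.5, 1, g)
  expect_equal(unlist(b), c(x_left = 4.5, x_right = 6.5,
                            y_bottom = 4.5, y_top = 6.5))
  b2 <- compute_cell_bounds(0, 0, 2, g)
  expect_equal(unlist(b2), c(x_left = -2, x_right = 2,
                             y_bottom = -2, y_top = 2))
  ga <- grid_spec(20, 20, w = 2, h = 0.5)
  b3 <- compute_cell_bounds(3, 3, 1, ga)
  expect_equal(unlist(b3), c(x_left = 2.5, x_right = 3.5,
                             y_bottom = 1, y_top = 5))
  expect_error(compute_cell_bounds(1, 1, 0, g), "radius")
  expect_error(compute_cell_bounds(1, 1, -1, g), "radius")
})

test_that("rasterization reproduces hand-computed footprints", {
  g <- grid_spec(20, 20)
  rc <- rasterize_cell(5.5, 5.5, 1, g)
  expect_equal(nrow(rc), 9)
  expect_equal(sum(rc$frac), 4)
  frac_at <- function(i, j) rc$frac[rc$i == i & rc$j == j]
  expect_equal(frac_at(5, 5), 1)            # center
  expect_equal(frac_at(4, 5), 0.5)          # edge midpoints
  expect_equal(frac_at(5, 6), 0.5)
  expect_equal(frac_at(4, 4), 0.25)         # corners
  expect_equal(frac_at(6, 6), 0.25)

  rc2 <- rasterize_cell(5, 5, 0.5, g)
  expect_equal(nrow(rc2), 4)
  expect_equal(rc2$frac, rep(0.25, 4))
  expect_equal(sum(rc2$frac), 1)
})

test_that("rasterized fractions match quadrature and sum to (2r/w)(2r/h)", {
  set.seed(11)
  g <- grid_spec(30, 30, w = 1, h = 1)
  for (k in 1:8) {
    xc <- runif(1, 5, 25); yc <- runif(1, 5, 25); r <- runif(1, 0.4, 2.5)
    rc <- rasterize_cell(xc, yc, r, g)
    expect_true(all(rc$frac >= 0 & rc$frac <= 1))
    expect_equal(sum(rc$frac), (2 * r)^2, tolerance = 1e-12)
    # spot-check three units against midpoint quadrature
    for (n in sample(nrow(rc), 3))
      expect_equal(rc$frac[n],
                   quadrature_occupancy(xc, yc, r, r, rc$i[n], rc$j[n]),
                   tolerance = 2e-2)
  }
  # anisotropic units: sum is (2r/w)(2r/h)
  ga <- grid_spec(40, 40, w = 2, h = 0.5)
  rc <- rasterize_cell(10, 10, 1.2, ga)
  expect_equal(sum(rc$frac), (2 * 1.2 / 2) * (2 * 1.2 / 0.5), tolerance = 1e-12)
})

test_that("degenerate rasterization inputs are signalled", {
  g <- grid_spec(10, 10, boundary = "open")
  expect_warning(out <- rasterize_cell(50, 50, 1, g), "outside")
  expect_equal(nrow(out), 0)
  expect_warning(rasterize_cell(5, 5, 0.01, g), "noisy")
  expect_error(build_occupancy(make_cells(5, 5, 20), g), "larger than the domain")
})

test_that("occupancy is additive, order-independent and wraps periodically", {
  g <- grid_spec(20, 20)
  expect_equal(build_occupancy(make_cells(numeric(0), numeric(0), numeric(0)), g),
               matrix(0, 20, 20), ignore_attr = TRUE)

  # two coincident cells double the single-cell footprint
  one <- build_occupancy(make_cells(5.5, 5.5, 1), g)
  two <- build_occupancy(make_cells(c(5.5, 5.5), c(5.5, 5.5), 1), g)
  expect_equal(unclass(two), unclass(one) * 2, ignore_attr = TRUE)
  expect_equal(max(two), 2)

  # disjoint cells: union of footprints, no unit above 1
  cl <- make_cells(c(4, 14.2), c(4, 9.7), 1)
  om <- build_occupancy(cl, g)
  expect_lte(max(om), 1)
  expect_equal(sum(om), 8, tolerance = 1e-12)

  # cpp path agrees with the R single-cell rasterizer
  set.seed(7)
  for (k in 1:5) {
    xc <- runif(1, 0, 20); yc <- runif(1, 0, 20); r <- runif(1, 0.5, 2)
    rc <- rasterize_cell(xc, yc, r, g)
    om1 <- build_occupancy(make_cells(xc * g$w, yc * g$h, r), g)
    om2 <- matrix(0, 20, 20)
    # rasterize_cell can emit duplicate (i, j) entries when a footprint wraps
    for (n in seq_len(nrow(rc)))
      om2[rc$i[n] + 1, rc$j[n] + 1] <- om2[rc$i[n] + 1, rc$j[n] + 1] + rc$frac[n]
    expect_equal(unclass(om1), om2, ignore_attr = TRUE, tolerance = 1e-12)
  }

  # mass rasterized across a periodic edge is conserved
  edge <- make_cells(c(0.3, 19.6), c(19.8, 0.2), c(1.2, 0.9))
  ome <- build_occupancy(edge, g)
  expect_equal(sum(ome), (2 * 1.2)^2 + (2 * 0.9)^2, tolerance = 1e-12)
})
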