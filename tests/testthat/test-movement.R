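test_that("unit motion vectors difference opposing layers", {
  g <- grid_spec(5, 5)
  m <- new_motion_tensor(g)
  m[3, 3, ] <- c(0, 0.2, 0, 0.1)   # down, right, up, left
  expect_equal(unname(unit_motion_vector(m, 2, 2)), c(0.1, 0))
  m[3, 3, ] <- c(0.4, 0.4, 0.4, 0.4)
  expect_equal(unname(unit_motion_vector(m, 2, 2)), c(0, 0))
  m[3, 3, ] <- c(0, 0, 0.3, 0)
  expect_equal(unname(unit_motion_vector(m, 2, 2)), c(0, 0.3))
})

test_that("single-occupancy movement sums per-unit vectors over the footprint", {
  g <- grid_spec(10, 10)
  cl <- make_cells(4.5, 4.5, 0.95)          # covers units (3..5)^2
  m <- new_motion_tensor(g)
  m[4, 4, ] <- c(0, 0.1, 0, 0)              # v = (0.1, 0)
  m[5, 5, ] <- c(0.03, 0.05, 0.05, 0)       # v = (0.05, 0.02)
  mv <- cell_movements(cl, m, g)
  expect_equal(mv$vx, 0.15)
  expect_equal(mv$vy, 0.02)

  # zero tensor -> no movement
  mv0 <- cell_movements(cl, new_motion_tensor(g), g)
  expect_equal(c(mv0$vx, mv0$vy), c(0, 0))
})

test_that("coincident cells split a symmetric tensor into opposite equal moves", {
  g <- grid_spec(20, 20)
  cc <- make_cells(c(10.3, 10.3), c(10.4, 10.4), 1)
  before <- overlap_ratio(cc, g)
  out <- dora_resolve_overlaps(cc, g)
  d1 <- sqrt((out$x[1] - cc$x[1])^2 + (out$y[1] - cc$y[1])^2)
  d2 <- sqrt((out$x[2] - cc$x[2])^2 + (out$y[2] - cc$y[2])^2)
  expect_gt(d1, 0)
  expect_equal(d1, d2, tolerance = 1e-9)
  dist <- sqrt(diff(out$x)^2 + diff(out$y)^2)
  expect_gt(dist, 0)
  expect_lt(overlap_ratio(out, g), before)
})

test_that("applying movements wraps periodic edges and clamps solid ones", {
  g <- grid_spec(10, 10)
  cl <- make_cells(9.8, 5, 0.5)
  mv <- data.frame(id = 1L, vx = 0.5, vy = 0)
  out <- apply_movements(cl, mv, g)
  expect_equal(out$x, 0.3, tolerance = 1e-12)

  gs <- grid_spec(10, 10, boundary = list(bottom = "solid", top = "open",
                                          left = "periodic", right = "periodic"))
  cl2 <- make_cells(5, 1, 1)
  mv2 <- data.frame(id = 1L, vx = 0, vy = -0.5)
  out2 <- apply_movements(cl2, mv2, gs)
  expect_equal(out2$y, 1)                      # clamped at one radius

  out3 <- apply_movements(cl, data.frame(id = 1L, vx = 0, vy = 0), g)
  expect_equal(out3$x, cl$x)
  expect_equal(out3$y, cl$y)
})

test_that("the resolver is the identity on occupancy-feasible populations", {
  g <- grid_spec(40, 40)
  # cells on a jittered lattice: bounding squares disjoint, so no grid
  # unit exceeds occupancy one (the square approximation means circle
  # disjointness alone does not guarantee feasibility)
  set.seed(5)
  ctr <- expand.grid(x = seq(3, 37, by = 5), y = seq(3, 37, by = 5))
  keep <- sample(nrow(ctr), 25)
  pk <- make_cells(ctr$x[keep] + runif(25, -0.5, 0.5),
                   ctr$y[keep] + runif(25, -0.5, 0.5),
                   runif(25, 0.8, 1.5))
  om <- build_occupancy(pk, g)
  expect_lte(max(om), 1)
  out <- dora_resolve_overlaps(pk, g)
  expect_equal(out$x, pk$x, tolerance = 1e-12)
  expect_equal(out$y, pk$y, tolerance = 1e-12)

  single <- make_cells(17.3, 22.8, 1.4)
  outs <- dora_resolve_overlaps(single, g)
  expect_equal(outs$x, single$x)
  expect_equal(outs$y, single$y)
})

test_that("two overlapping cells separate monotonically until resolved", {
  g <- grid_spec(20, 20)
  cl <- make_cells(c(10, 10.5), c(10, 10), 1)
  area0 <- brute_overlap_area(cl)
  d_prev <- 0.5
  cur <- cl
  for (k in 1:25) {
    cur <- dora_resolve_overlaps(cur, g)
    d <- sqrt(diff(cur$x)^2 + diff(cur$y)^2)
    expect_gte(d, d_prev - 1e-9)
    d_prev <- d
  }
  expect_lt(brute_overlap_area(cur), area0)
  expect_gte(d_prev, 2)                        # pairwise overlap eliminated
})

test_that("repeated resolver calls drive a dense packing below 1% overlap", {
  pk <- generate_packing(50, domain = c(60, 60), radius_range = c(1, 2),
                         target_overlap_ratio = 0.06, seed = 9)
  expect_gt(brute_overlap_ratio(pk), 0.05)
  g <- grid_spec(60, 60)
  cur <- pk
  for (k in 1:20) {
    cur <- dora_resolve_overlaps(cur, g)
    if (brute_overlap_ratio(cur) < 0.01) break
  }
  expect_lt(brute_overlap_ratio(cur), 0.01)
})

test_that("Moore diagonal layers fold into the cardinal components", {
  g <- grid_spec(12, 12)
  cfg <- resolution_config(neighborhood = "moore")
  set.seed(83)
  m <- new_motion_tensor(g, cfg)
  m[] <- runif(length(m), 0, 0.05)
  # single cell covering a 2x2 block of units: its movement must equal the
  # sum of the per-unit vectors, diagonals contributing 1/sqrt(2) each
  cl <- make_cells(6, 6, 1)
  mv <- cell_movements(cl, m, g, cfg)
  v <- unit_motion_vectors(m)
  units <- cbind(c(6, 7, 6, 7), c(6, 7, 7, 6))   # 1-based indices of units (5..6, 5..6)
  expect_equal(mv$vx, sum(v$vx[units]), tolerance = 1e-12)
  expect_equal(mv$vy, sum(v$vy[units]), tolerance = 1e-12)
})

test_that("the fused resolver equals the staged pipeline", {
  set.seed(77)
  for (case in 1:4) {
    nb <- if (case %% 2 == 0) "moore" else "von_neumann"
    # uncapped so the composition of the staged operations is exact
    cfg <- resolution_config(neighborhood = nb, max_move = Inf)
    g <- grid_spec(50, 50, boundary = if (case > 2) "periodic" else "open")
    pk <- generate_packing(30, domain = c(50, 50), radius_range = c(1, 2),
                           target_overlap_ratio = 0.08)
    fused <- suppressWarnings(dora_resolve_overlaps(pk, g, cfg))
    om <- build_occupancy(pk, g)
    res <- suppressWarnings(resolve_occupancy(om, cfg, g))
    mv <- cell_movements(pk, res$motion, g, cfg)
    staged <- apply_movements(pk, mv, g)
    expect_equal(fused$x, staged$x, tolerance = 1e-12)
    expect_equal(fused$y, staged$y, tolerance = 1e-12)
    expect_equal(attr(fused, "iterations"), res$iterations)
  }
})

test_that("jitter is seeded and only active when requested", {
  g <- grid_spec(30, 30)
  pk <- generate_packing(10, domain = c(30, 30), seed = 3)
  cfg <- resolution_config(jitter_sigma = 0.1)
  set.seed(99); a <- dora_resolve_overlaps(pk, g, cfg)
  set.seed(99); b <- dora_resolve_overlaps(pk, g, cfg)
  expect_identical(a$x, b$x)
  expect_false(identical(a$x, pk$x))           # jitter displaced the cells
})
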