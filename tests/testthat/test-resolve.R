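test_that("excess matrix clips occupancy at one", {
  om <- matrix(c(1.5, 0.8, 1.0, 0), 2, 2)
  expect_equal(compute_excess(om), matrix(c(0.5, 0, 0, 0), 2, 2))
})

test_that("uniform excess on a periodic grid is a fixed point", {
  g <- grid_spec(6, 6)
  om <- matrix(1.4, 6, 6)
  attr(om, "grid") <- g
  st <- diffuse_step(om)
  expect_equal(unclass(st$omega), unclass(om), ignore_attr = TRUE)
  expect_equal(st$max_delta, 0)
})

test_that("a single over-occupied unit redistributes per the update rule", {
  g <- grid_spec(7, 7)
  om <- matrix(0.5, 7, 7)
  om[4, 4] <- 1.4                      # excess 0.4, neighbors 0
  attr(om, "grid") <- g
  cfg <- resolution_config(alpha = 0.5)
  st <- diffuse_step(om, cfg)
  expect_equal(st$omega[4, 4], 1.4 - 0.2)        # loses alpha * E
  expect_equal(st$omega[3, 4], 0.5 + 0.05)       # each neighbor gains alpha/4 * E
  expect_equal(st$omega[5, 4], 0.55)
  expect_equal(st$omega[4, 3], 0.55)
  expect_equal(st$omega[4, 5], 0.55)
  expect_equal(st$motion[4, 4, ], rep(0.05, 4))  # all four layers
  # motion is zero elsewhere (no other unit has positive excess)
  st$motion[4, 4, ] <- 0
  expect_equal(max(abs(st$motion)), 0)
})

test_that("diffusion conserves total occupancy on periodic grids", {
  set.seed(21)
  for (k in 1:100) {
    om <- random_omega(sample(4:12, 1), sample(4:12, 1))
    st <- diffuse_step(om)
    expect_equal(sum(st$omega), sum(om), tolerance = 1e-9)
  }
  # Moore neighborhood conserves as well
  for (k in 1:20) {
    om <- random_omega(8, 8)
    st <- diffuse_step(om, resolution_config(neighborhood = "moore"))
    expect_equal(sum(st$omega), sum(om), tolerance = 1e-9)
  }
})

test_that("the compiled iteration loop matches repeated R diffusion steps", {
  set.seed(31)
  for (nb in c("von_neumann", "moore")) {
    cfg <- resolution_config(neighborhood = nb, alpha = 0.4)
    om <- random_omega(9, 7)
    g <- grid_spec(9, 7)
    # force exactly k iterations of the compiled loop
    k <- 5
    cfgk <- resolution_config(neighborhood = nb, alpha = 0.4,
                              tol = 1e-300, max_iters = k)
    res <- suppressWarnings(resolve_occupancy(om, cfgk, grid = g))
    omr <- om
    mot <- new_motion_tensor(g, cfg)
    for (i in seq_len(k)) {
      st <- diffuse_step(omr, cfg, mot, grid = g)
      omr <- st$omega
      mot <- st$motion
    }
    expect_equal(res$omega, unclass(omr), ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(as.vector(res$motion), as.vector(mot), tolerance = 1e-12)
  }
})

test_that("resolve terminates immediately without excess", {
  g <- grid_spec(10, 10)
  zero <- matrix(0, 10, 10)
  res <- resolve_occupancy(zero, grid = g)
  expect_equal(res$iterations, 1)
  expect_equal(max(abs(res$motion)), 0)

  feasible <- matrix(runif(100, 0, 1), 10, 10)
  res2 <- resolve_occupancy(feasible, grid = g)
  expect_equal(max(abs(res2$motion)), 0)
})

test_that("an isolated over-occupied unit yields a four-fold symmetric tensor", {
  g <- grid_spec(9, 9)
  om <- matrix(0, 9, 9)
  om[5, 5] <- 1.8
  res <- resolve_occupancy(om, grid = g)
  expect_gt(res$iterations, 1)
  m <- res$motion
  expect_equal(m[5, 5, 1], m[5, 5, 2])
  expect_equal(m[5, 5, 2], m[5, 5, 3])
  expect_equal(m[5, 5, 3], m[5, 5, 4])
  expect_gt(m[5, 5, 1], 0)
})

test_that("the motion tensor is equivariant under 90-degree rotation", {
  set.seed(41)
  g <- grid_spec(8, 8)
  cfg <- resolution_config(tol = 1e-300, max_iters = 4)
  # rotating the occupancy by 90 deg (x', y') = (-y, x) permutes the
  # motion layers down/right/up/left -> right/up/left/down
  rot90 <- function(m) t(m[, rev(seq_len(ncol(m)))])  # maps (i,j) -> (n-1-j, i)
  for (k in 1:5) {
    om <- random_omega(8, 8)
    r1 <- suppressWarnings(resolve_occupancy(om, cfg, grid = g))
    r2 <- suppressWarnings(resolve_occupancy(rot90(om), cfg, grid = g))
    expect_equal(r2$omega, rot90(r1$omega), tolerance = 1e-12)
    perm <- c(2, 3, 4, 1)   # layer of rotated field = rotated original layer
    for (d in 1:4)
      expect_equal(r2$motion[, , perm[d]], rot90(r1$motion[, , d]),
                   tolerance = 1e-12)
  }
})
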