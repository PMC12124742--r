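test_that("scenario construction matches the study designs", {
  col <- build_scenario("colony", 100)
  expect_equal(col$domain, c(600, 600))
  expect_equal(nrow(col$initial_cells), 1)
  expect_equal(col$initial_cells$x, 300)
  expect_equal(col$initial_cells$y, 300)
  expect_true(all(unlist(col$grid$boundary) == "periodic"))

  bio <- build_scenario("biofilm", 10)
  expect_equal(bio$domain, c(800, 200))
  expect_equal(nrow(bio$initial_cells), 40)
  expect_true(all(bio$initial_cells$y == bio$growth$initial_radius))
  expect_equal(bio$grid$boundary$bottom, "solid")
  expect_equal(bio$field$boundary$top, "dirichlet")

  sc <- build_scenario("colony", 100, overrides = list(domain_scale = 0.25))
  expect_equal(sc$domain, c(150, 150))
  expect_equal(sc$grid$W, 150L)

  expect_error(build_scenario("plate", 100))
  expect_error(build_scenario("colony", 100,
                              overrides = list(dt_fast = 3e-3)),
               "divide")
  expect_error(build_scenario("colony", 100,
                              overrides = list(field = list(dx = 2))),
               "unstable")
})

test_that("a zero-nutrient scenario is a fixed point", {
  sc <- build_scenario("colony", 0,
                       overrides = list(domain_scale = 0.1, duration = 1,
                                        seed = 1))
  st <- run_simulation(sc)
  expect_equal(nrow(st$cells), 1)
  expect_equal(st$cells$x, sc$initial_cells$x)
  expect_equal(st$cells$y, sc$initial_cells$y)
  expect_equal(st$cells$biomass, sc$initial_cells$biomass)
})

test_that("abundant nutrient gives exponential growth at the Monod rate", {
  # population doubling cadence within 5% of ln 2 / mu(S0) before crowding
  # mu_max raised so several doublings fit in a short run; the check is
  # the exponential cadence itself, not a particular rate
  sc <- build_scenario("colony", 1e4,
                       overrides = list(domain_scale = 0.25, duration = 80,
                                        seed = 2, stop_population = 100,
                                        stall_stop = FALSE,
                                        growth = list(mu_max = 0.1)))
  st <- run_simulation(sc)
  m <- st$metrics
  m <- m[m$population >= 8 & m$population <= 128, ]
  fit <- lm(log(population) ~ time, data = m)
  mu_hat <- unname(coef(fit)[2])
  mu_exp <- monod_rate(1e4, sc$growth)
  expect_lt(abs(mu_hat - mu_exp) / mu_exp, 0.05)
})

test_that("stepping a small colony keeps overlaps controlled by either resolver", {
  base <- generate_packing(10, domain = c(30, 60), radius_range = c(1, 1.4),
                           seed = 3)
  for (type in c("dora", "kdtree")) {
    sc <- build_scenario("colony", 100,
                         overrides = list(domain = c(60, 60), seed = 4,
                                          resolver = list(type = type),
                                          initial_cells = base,
                                          duration = 10))
    sc$initial_cells$biomass <- biomass_from_radius(sc$initial_cells$r,
                                                    sc$growth)
    set.seed(4)
    state <- init_simulation(sc)
    for (k in 1:20) {
      state <- step_simulation(state, sc)
      if (type == "kdtree") {
        pr <- brute_pairs(state$cells, 60, 60, TRUE, TRUE)
        if (nrow(pr) > 0)
          expect_lt(max(state$cells$r[pr$i] + state$cells$r[pr$j] - pr$d),
                    sc$resolver$shove_tol + 1e-9)
      } else {
        expect_lt(brute_overlap_ratio(state$cells, 60, 60, TRUE, TRUE), 0.01)
      }
    }
    expect_gte(nrow(state$cells), 10)   # population non-decreasing
  }
})

test_that("starving cells are removed only when lysis is enabled", {
  base <- list(domain_scale = 0.1, duration = 0.5, seed = 9)
  sc0 <- build_scenario("colony", 0, overrides = base)
  st0 <- run_simulation(sc0)
  expect_equal(nrow(st0$cells), 1)            # no lysis by default
  sc1 <- build_scenario("colony", 0,
                        overrides = c(base, list(growth = list(lysis_conc = 0.5))))
  st1 <- run_simulation(sc1)
  expect_equal(nrow(st1$cells), 0)            # starved below the threshold
})

test_that("area-weighted sink spreading conserves the consumed mass", {
  ov <- list(domain_scale = 0.2, duration = 1, seed = 10,
             sink_spread = "area")
  sc <- build_scenario("colony", 100, overrides = ov)
  st <- init_simulation(sc)
  set.seed(10)
  st <- step_simulation(st, sc)               # growth records the sinks
  consumed_conc <- sum(st$sinks) * sc$nsub    # per-substep sinks, summed
  mu <- monod_rate(100, sc$growth)
  m0 <- sc$initial_cells$biomass
  expect_gt(consumed_conc, 0)
  expect_equal(consumed_conc,
               (m0 * exp(mu * sc$dt_slow) - m0) / sc$growth$yield *
                 sc$conc_per_pg,
               tolerance = 1e-9)
})

test_that("runs are deterministic under a fixed seed", {
  sc <- build_scenario("colony", 100,
                       overrides = list(domain_scale = 0.2, duration = 80,
                                        seed = 7))
  a <- run_simulation(sc)
  b <- run_simulation(sc)
  expect_identical(a$cells, b$cells)
  expect_identical(a$metrics$overlap_ratio, b$metrics$overlap_ratio)
})

test_that("nutrient regimes shape colony morphology", {
  # high nutrient with fast (default) diffusion: compact, near-circular
  sc_hi <- build_scenario("colony", 100,
                          overrides = list(domain_scale = 0.15,
                                           duration = 400,
                                           stop_population = 150, seed = 107))
  hi <- suppressWarnings(run_simulation(sc_hi))
  expect_gte(nrow(hi$cells), 150)
  expect_lt(edge_roughness(hi$cells), 0.15)

  # under slow effective diffusivity (dense-matrix regime, D = 1 um^2/min)
  # nutrient limitation roughens the edge relative to a rich colony of the
  # same size: diffusion-limited competition feeds protruding cells first
  rough <- vapply(c(100, 10), function(nut) {
    sc <- build_scenario("colony", nut,
                         overrides = list(domain_scale = 0.1, duration = 900,
                                          stop_population = 80, seed = 109,
                                          field = list(D = 1)))
    st <- suppressWarnings(run_simulation(sc))
    expect_equal(nrow(st$cells), 80)
    edge_roughness(st$cells)
  }, numeric(1))
  expect_gt(rough[2], rough[1])
})

test_that("biofilm growth stays above the solid floor and below the lid", {
  sc <- build_scenario("biofilm", 100,
                       overrides = list(domain_scale = 0.25, duration = 60,
                                        seed = 8))
  st <- run_simulation(sc)
  expect_gte(nrow(st$cells), 10)
  expect_true(all(st$cells$y >= st$cells$r - 1e-9))
  # Dirichlet top edge held at bulk concentration throughout
  expect_equal(st$field$S[, ncol(st$field$S)],
               rep(100, nrow(st$field$S)))
})
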