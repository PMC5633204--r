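gp <- growth_params()

test_that("tumor_rhs reproduces its fixed points and the logistic rate", {
  g <- tiny_grid(8)
  zero <- scalar_field(g, 0)
  one <- scalar_field(g, 1)

  expect_equal(tumor_rhs(zero, one, zero, gp)$values, matrix(0, 8, 8))

  nlim <- scalar_field(g, gp$n_lim)
  expect_equal(tumor_rhs(nlim, zero, zero, gp)$values, matrix(0, 8, 8))

  n01 <- scalar_field(g, 0.1 * gp$n_lim)
  expect_equal(tumor_rhs(n01, zero, zero, gp)$values,
               matrix(gp$r * 0.1 * gp$n_lim * 0.9, 8, 8), tolerance = 1e-13)

  # chemotherapy kill term enters at the converted per-day rate
  d <- scalar_field(g, 0.5)
  expect_equal(tumor_rhs(one, zero, d, gp)$values,
               matrix(-gp$d_r_day * 0.5, 8, 8), tolerance = 1e-13)
})

test_that("growth-inhibition variant gates the growth terms", {
  g <- tiny_grid(8)
  n <- scalar_field(g, 0.4)
  m <- scalar_field(g, 0.8)
  d <- scalar_field(g, 0.3)
  base_growth <- gp$r * 0.4 * (1 - 0.4) + gp$alpha_mn * 0.4 * 0.8

  v <- tumor_rhs(n, m, d, gp, inhibition_variant = TRUE, d_max = 0.6)
  expect_equal(v$values, matrix(base_growth * (1 - 0.3 / 0.6), 8, 8),
               tolerance = 1e-13)

  # keep_kill retains the cytotoxic term alongside the gating
  vk <- tumor_rhs(n, m, d, gp, inhibition_variant = TRUE, d_max = 0.6,
                  keep_kill = TRUE)
  expect_equal(vk$values - v$values, matrix(-gp$d_r_day * 0.4 * 0.3, 8, 8),
               tolerance = 1e-13)

  expect_error(tumor_rhs(n, m, d, gp, inhibition_variant = TRUE, d_max = 0),
               "d_max")
})

test_that("vessel_rhs fixed points and agent kill", {
  g <- tiny_grid(8)
  zero <- scalar_field(g, 0)
  one <- scalar_field(g, 1)

  expect_equal(vessel_rhs(zero, one, zero, gp)$values, matrix(0, 8, 8))
  # m = 1 is a root because alpha + beta + gamma = 0
  expect_equal(vessel_rhs(one, zero, zero, gp)$values, matrix(0, 8, 8),
               tolerance = 1e-14)
  expect_equal(vessel_rhs(one, zero, one, gp)$values,
               matrix(-gp$A_r_day, 8, 8), tolerance = 1e-12)
})

test_that("step_growth honors dt = 0, the stability bound, and the scalar
           logistic oracle", {
  g <- tiny_grid(8, h = 0.05)
  state <- list(n = scalar_field(g, 0.2), m = scalar_field(g, 0))
  drugs <- list(A = scalar_field(g, 0), d = scalar_field(g, 0))

  expect_identical(step_growth(state, drugs, gp, 0), state)

  dt_max <- max_stable_dt(g, gp)
  expect_error(step_growth(state, drugs, gp, dt_max * 1.01), "stability")

  dt <- min(0.01, dt_max)
  out <- step_growth(state, drugs, gp, dt)
  scalar_euler <- 0.2 + dt * gp$r * 0.2 * (1 - 0.2 / gp$n_lim)
  expect_equal(out$n$values, matrix(scalar_euler, 8, 8), tolerance = 1e-13)
})

test_that("step_growth is first order: halving dt shrinks the step
           difference ~4x", {
  g <- tiny_grid(12, h = 0.1)
  co <- grid_coords(g)
  smooth <- scalar_field(g, 0.3 + 0.2 * sin(2 * pi * co$x) *
                           sin(2 * pi * co$y) * 0.5 + 0.1)
  state <- list(n = smooth, m = scalar_field(g, 0.8))
  drugs <- list(A = scalar_field(g, 0), d = scalar_field(g, 0))
  two_half_vs_one <- function(dt) {
    one <- step_growth(state, drugs, gp, dt)
    half <- step_growth(step_growth(state, drugs, gp, dt / 2),
                        drugs, gp, dt / 2)
    max(abs(one$n$values - half$n$values),
        abs(one$m$values - half$m$values))
  }
  e1 <- two_half_vs_one(0.02)
  e2 <- two_half_vs_one(0.01)
  expect_gt(e1 / e2, 3)   # O(dt^2) difference
  expect_lt(e1 / e2, 5)
})

test_that("uniform fixed points persist and densities stay nonnegative", {
  g <- tiny_grid(8, h = 0.05)
  drugs0 <- list(A = scalar_field(g, 0), d = scalar_field(g, 0))
  dt <- min(0.01, max_stable_dt(g, gp))
  st <- list(n = scalar_field(g, gp$n_lim), m = scalar_field(g, 0))
  for (i in 1:5) st <- step_growth(st, drugs0, gp, dt)
  expect_equal(st$n$values, matrix(gp$n_lim, 8, 8), tolerance = 1e-12)
  expect_equal(st$m$values, matrix(0, 8, 8))

  # violent drug exposure: clamped to zero, never negative
  st <- list(n = scalar_field(g, 0.01), m = scalar_field(g, 0.01))
  harsh <- list(A = scalar_field(g, 50), d = scalar_field(g, 50))
  for (i in 1:3) st <- step_growth(st, harsh, gp, dt)
  expect_true(all(st$n$values >= 0))
  expect_true(all(st$m$values >= 0))
})

test_that("vessel coupling accelerates growth; agent exposure shrinks
           vessels monotonically", {
  g <- tiny_grid(8, h = 0.05)
  dt <- min(0.01, max_stable_dt(g, gp))
  drugs0 <- list(A = scalar_field(g, 0), d = scalar_field(g, 0))

  with_m <- list(n = scalar_field(g, 0.3), m = scalar_field(g, 1))
  no_m <- list(n = scalar_field(g, 0.3), m = scalar_field(g, 0))
  for (i in 1:10) {
    with_m <- step_growth(with_m, drugs0, gp, dt)
    no_m <- step_growth(no_m, drugs0, gp, dt)
  }
  expect_true(all(with_m$n$values > no_m$n$values))

  st <- list(n = scalar_field(g, 0), m = scalar_field(g, 1))
  agent <- list(A = scalar_field(g, 0.5), d = scalar_field(g, 0))
  means <- numeric(10)
  for (i in 1:10) {
    st <- step_growth(st, agent, gp, dt)
    means[i] <- mean(st$m$values)
  }
  expect_true(all(diff(means) < 0))
})

test_that("Gaussian tumor initializer hits its contour contract", {
  g <- grid_2d(101, 101, h = 0.01)
  f <- init_tumor_gaussian(g, radius0 = 0.2, peak = 0.8)
  ctr <- g$origin + grid_extent(g) / 2
  co <- grid_coords(g)
  i_ctr <- which.min(abs(co$x[, 1] - ctr[1]))
  expect_equal(f$values[i_ctr, i_ctr], 0.8)
  # value on the radius0 circle is 0.1 * peak (check on-axis node)
  i_edge <- which.min(abs(co$x[, 1] - (ctr[1] + 0.2)))
  expect_equal(f$values[i_edge, i_ctr], 0.08, tolerance = 1e-10)
  # paper-scale default: 0.2 mm
  expect_equal(formals(init_tumor_gaussian)$radius0, 0.02)
  expect_error(init_tumor_gaussian(g, radius0 = 0.6), "half the domain")
})

test_that("vessel islands are deterministic and settle onto the bistable
           states", {
  g <- grid_2d(40, 40, h = 0.05)
  m1 <- init_vessel_islands(g, seed = 5)
  m2 <- init_vessel_islands(g, seed = 5)
  expect_identical(m1$values, m2$values)

  raw <- init_vessel_islands(g, seed = 5, relax_time = 0)
  expect_true(all(raw$values > 0 & raw$values < 1))
  expect_false(identical(raw$values,
                         init_vessel_islands(g, seed = 6,
                                             relax_time = 0)$values))

  settled <- mean(abs(m1$values) < 0.05 | abs(m1$values - 1) < 0.05)
  expect_gte(settled, 0.99)
})
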