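fp <- fluid_params()

test_that("effective conductivities switch between the tabulated columns", {
  # healthy tissue: inherent vessels, working lymphatics
  sc <- uniform_scene(0, 0.5)
  expect_equal(sc$cf$lambda_b$values, matrix(2.52e-6, 9, 9))
  expect_equal(sc$cf$lambda_l$values, matrix(6.66e-4, 9, 9))
  expect_equal(sc$cf$osmotic$values, matrix(9.1, 9, 9))

  # angiogenic tumor: leaky walls, no lymphatics, collapsed oncotic gap
  sc <- uniform_scene(1, 1.5)
  expect_equal(sc$cf$lambda_b$values, matrix(3.72e-4, 9, 9))
  expect_equal(sc$cf$lambda_l$values, matrix(0, 9, 9))
  expect_equal(sc$cf$osmotic$values, matrix(2.2e-4, 9, 9))

  # ramp midpoint: lambda_b midway between the two derived products
  sc <- uniform_scene(0, 1.05)
  expect_equal(sc$cf$lambda_b$values,
               matrix((2.52e-6 + 3.72e-4) / 2, 9, 9))
  expect_equal(sc$cf$ramp_w$values, matrix(0.5, 9, 9))

  expect_error(effective_conductivities(scalar_field(tiny_grid(), -1),
                                        scalar_field(tiny_grid(), 1), fp),
               "nonnegative")
})

test_that("Starling source and lymph sink follow their closed forms", {
  sc <- uniform_scene(1, 1.5)  # tumor column
  Peq <- scalar_field(sc$g, fp$P_v - 2.2e-4, unit = "mmHg")
  expect_equal(starling_source(sc$m, Peq, sc$cf, fp)$values,
               matrix(0, 9, 9), tolerance = 1e-18)

  zero_m <- scalar_field(sc$g, 0)
  P0 <- scalar_field(sc$g, 0, unit = "mmHg")
  expect_equal(starling_source(zero_m, P0, sc$cf, fp)$values, matrix(0, 9, 9))

  sc1 <- uniform_scene(1, 1.5)
  gb <- starling_source(scalar_field(sc1$g, 1), P0, sc1$cf, fp)
  expect_equal(gb$values, matrix(3.72e-4 * (15 - 2.2e-4), 9, 9),
               tolerance = 1e-12)  # ~5.58e-3 /s

  # lymph sink
  scn <- uniform_scene(0, 0.5)
  P10 <- scalar_field(scn$g, 10, unit = "mmHg")
  expect_equal(lymph_sink(P10, scn$cf)$values, matrix(6.66e-3, 9, 9))
  expect_equal(lymph_sink(P0, scn$cf)$values, matrix(0, 9, 9))
  sct <- uniform_scene(1, 1.5)  # lymphatics suppressed inside tumor
  expect_equal(lymph_sink(P10, sct$cf)$values, matrix(0, 9, 9))
})

test_that("solve_ifp reproduces uniform equilibria and flags singularity", {
  # uniform leaky tumor, no lymph: P = P_eff,t is the exact solution
  sc <- uniform_scene(1, 1.5, nx = 15)
  Pt <- fp$P_v - 2.2e-4
  P <- solve_ifp(sc$m, sc$cf, fp, bc_dirichlet(Pt))
  expect_equal(P$values, matrix(Pt, 15, 15), tolerance = 1e-10)

  # no vessels anywhere, lymph active, zero boundary: P = 0
  sc0 <- uniform_scene(0, 0, nx = 15)
  P0 <- solve_ifp(sc0$m, sc0$cf, fp, bc_dirichlet(0))
  expect_equal(P0$values, matrix(0, 15, 15))

  # all exchange terms zero + pure no-flux: constant null space
  g <- tiny_grid(9)
  cf_dead <- structure(list(
    lambda_b = scalar_field(g, 0, "1/mmHg.s"),
    lambda_l = scalar_field(g, 0, "1/mmHg.s"),
    osmotic = scalar_field(g, 0, "mmHg"),
    ramp_w = scalar_field(g, 0), delta = 0.1, n_tum = 0.1),
    class = "an_conductivities")
  expect_error(solve_ifp(scalar_field(g, 0), cf_dead, fp, bc_no_flux()),
               "singular")
})

test_that("solved pressure obeys the maximum principle", {
  fx <- make_fixture("disc_tumor", nx = 41, extent = 1.5, R = 0.4)
  P <- solve_ifp(fx$m, fx$cf, fx$fp)
  expect_gte(min(P$values), 0)
  expect_lte(max(P$values), fp$P_eff_tumor + 1e-9)
})

test_that("transvascular supply balances lymph drainage plus boundary
           outflux", {
  fx <- make_fixture("disc_tumor", nx = 61, extent = 1.5, R = 0.4)
  P <- solve_ifp(fx$m, fx$cf, fx$fp)
  gb <- starling_source(fx$m, P, fx$cf, fx$fp)$values
  gl <- lymph_sink(P, fx$cf)$values
  h <- fx$grid$h
  inner <- 2:(fx$grid$nx - 1)
  net_supply <- sum((gb - gl)[inner, inner]) * h^2
  # Darcy flux through the faces between the interior block and the
  # Dirichlet boundary ring
  Pv <- P$values
  flux <- fp$K * (sum(Pv[2, inner] - Pv[1, inner]) +
                    sum(Pv[fx$grid$nx - 1, inner] - Pv[fx$grid$nx, inner]) +
                    sum(Pv[inner, 2] - Pv[inner, 1]) +
                    sum(Pv[inner, fx$grid$ny - 1] - Pv[inner, fx$grid$ny]))
  expect_equal(net_supply, flux, tolerance = 1e-8)
})

test_that("analytic radial oracle: symmetry, limits and plateau", {
  expect_error(analytic_ifp_radial(-1, fp, 0.1), "positive")

  p <- analytic_ifp_radial(0.5, fp, c(0, 1e-4, 0.25, 0.5))
  expect_equal(p[1], p[2], tolerance = 1e-9)  # flat at the centre
  expect_lt(p[1], fp$P_eff_tumor)

  # perfect-equilibration limit: enormous wall conductivity
  fp_hi <- fluid_params(L_p_tumor = 1.86e-2)
  p_hi <- analytic_ifp_radial(0.5, fp_hi, c(0, 0.4))
  expect_equal(p_hi, rep(fp_hi$P_eff_tumor, 2), tolerance = 1e-6)

  # Table-1 values, R = 0.5 cm: centre plateau within 5% of 15 mmHg
  expect_gt(analytic_ifp_radial(0.5, fp, 0), 0.95 * fp$P_eff_tumor)

  # far field decays to the healthy equilibrium
  expect_equal(analytic_ifp_radial(0.5, fp, 2),
               normal_equilibrium_pressure(fp), tolerance = 1e-6)
})

test_that("darcy velocity follows -K grad P", {
  g <- tiny_grid(11, h = 0.1)
  co <- grid_coords(g)
  u0 <- darcy_velocity(scalar_field(g, 4, unit = "mmHg"), fp)
  expect_equal(u0$ux$values, matrix(0, 11, 11))

  ul <- darcy_velocity(scalar_field(g, 2 * co$x, unit = "mmHg"), fp,
                       bc_dirichlet(0))
  expect_equal(ul$ux$values[2:10, 2:10], matrix(-fp$K * 2, 9, 9))
  expect_equal(ul$uy$values[2:10, 2:10], matrix(0, 9, 9))

  # radial profile: outward flow at the rim where dP/dr < 0
  fx <- make_fixture("disc_tumor", nx = 81, extent = 2, R = 0.5)
  P <- solve_ifp(fx$m, fx$cf, fx$fp)
  u <- darcy_velocity(P, fp)
  co <- grid_coords(fx$grid)
  ctr <- fx$center
  j_mid <- (fx$grid$ny + 1) %/% 2
  i_rim <- which.min(abs(co$x[, j_mid] - (ctr[1] + fx$R)))
  expect_gt(u$ux$values[i_rim, j_mid], 0)
})
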