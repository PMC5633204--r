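# Shared test scaffolding: small grids, deterministic random fields, and a
# session cache so the expensive acceptance pipelines (case comparison at
# 64x64, growth calibration at 151x151) run once and are reused.

tiny_grid <- function(nx = 9, h = 0.1) grid_2d(nx, nx, h = h)

rand_field <- function(g, seed, lo = 0, hi = 1, unit = "dimensionless") {
  set.seed(seed)
  scalar_field(g, matrix(runif(g$nx * g$ny, lo, hi), g$nx, g$ny), unit = unit)
}

# scalar reference implementation of div(coef grad f) with sealed boundary
# faces: plain loops, independent of the vectorized operator
dense_div_coef_grad <- function(coef, f) {
  g <- f$grid
  cv <- coef$values; fv <- f$values
  out <- matrix(0, g$nx, g$ny)
  at <- function(M, i, j) {
    # ghost equals the edge value, so the boundary-face flux vanishes
    i <- min(max(i, 1L), g$nx)
    j <- min(max(j, 1L), g$ny)
    M[i, j]
  }
  for (i in seq_len(g$nx)) for (j in seq_len(g$ny)) {
    fe <- 0.5 * (at(cv, i + 1, j) + cv[i, j]) * (at(fv, i + 1, j) - fv[i, j])
    fw <- 0.5 * (at(cv, i - 1, j) + cv[i, j]) * (fv[i, j] - at(fv, i - 1, j))
    fn <- 0.5 * (at(cv, i, j + 1) + cv[i, j]) * (at(fv, i, j + 1) - fv[i, j])
    fs <- 0.5 * (at(cv, i, j - 1) + cv[i, j]) * (fv[i, j] - at(fv, i, j - 1))
    out[i, j] <- (fe - fw + fn - fs) / g$h^2
  }
  out
}

# uniform "0-D" conductivity scene: constant n and m on a small grid
uniform_scene <- function(nv, mv, nx = 9, fp = fluid_params()) {
  g <- tiny_grid(nx)
  n <- scalar_field(g, nv)
  m <- scalar_field(g, mv)
  list(g = g, n = n, m = m, fp = fp,
       cf = effective_conductivities(n, m, fp))
}

an_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = an_test_cache))
    assign(key, force(expr), envir = an_test_cache)
  get(key, envir = an_test_cache)
}

# The desk-scale treatment comparison: calibrated antiangiogenic dose per
# regimen, all four reference cases run to day 31 on the 64x64 fixture.
acceptance_cases <- function() {
  cached("cases", {
    fix <- make_fixture("grown_tumor_small", seed = 3)
    out <- list(results = list(), peaks = list())
    for (cs in c("case1", "case2", "case3", "case4")) {
      cfg <- fix
      cfg$regimen <- build_regimen(cs, aa_peak = 0.3)
      if (cs != "case2") {
        cal <- calibrate_aa_dose(cfg, upper = 4)
        out$peaks[[cs]] <- cal$aa_peak
        out$reductions[[cs]] <- cal$reduction
        cfg$regimen <- rescale_aa_peak(cfg$regimen, cal$aa_peak)
      }
      out$results[[cs]] <- run_simulation(cfg, t_stop = 31)
    }
    out
  })
}

# Growth-rate calibration against the day-30 radius at full resolution.
acceptance_growth <- function() {
  cached("growth_cal", {
    cfg <- sim_config(nx = 151, seed = 7, metric_dt = 1)
    cal <- calibrate_growth(cfg)
    ctrl <- cfg
    ctrl$gp$r <- cal$r
    list(cal = cal, control = run_simulation(ctrl))
  })
}

# Grown-tumor state at 151x151 for the IFP phenomenology checks.
acceptance_grown <- function() {
  cached("grown151", {
    cfg <- sim_config(nx = 151, seed = 7, metric_dt = 1, radius0 = 0.15)
    run_simulation(cfg)
  })
}
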