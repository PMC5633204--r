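#' Right-hand side of the tumor-cell equation
#'
#' `dn/dt = D_n lap(n) + r n (1 - n/n_lim) + alpha_mn n m - d_r n d`.
#' Tumor cells diffuse, grow logistically, proliferate faster where vessels
#' supply nutrients, and are killed by the extravasated chemotherapy drug.
#'
#' With `inhibition_variant = TRUE` the drug is cytostatic instead of
#' cytotoxic: the logistic and vessel-assisted growth terms are multiplied by
#' `(1 - d/d_max)` and the kill term is dropped (set `keep_kill = TRUE` to
#' retain it alongside the inhibition).
#'
#' @param n,m,d Tumor, vessel and drug `an_field`s on one grid
#'   (d in tissue-concentration units, nonnegative).
#' @param p An `an_growth_params`.
#' @param inhibition_variant Logical; growth-inhibition drug action.
#' @param keep_kill Logical; keep `-d_r n d` under the variant.
#' @param d_max Concentration scale for the variant (overrides `p$d_max`).
#' @param bc Boundary condition for the diffusion operator.
#' @return An `an_field`, units 1/day.
#' @export
tumor_rhs <- function(n, m, d, p, inhibition_variant = FALSE,
                      keep_kill = FALSE, d_max = NULL, bc = bc_no_flux()) {
  check_same_grid(n, m, d)
  if (any(d$values < 0)) stop("drug field d must be nonnegative")
  nv <- n$values
  growth <- p$r * nv * (1 - nv / p$n_lim) + p$alpha_mn * nv * m$values
  if (inhibition_variant) {
    dm <- if (!is.null(d_max)) d_max else p$d_max
    if (is.null(dm) || is.na(dm) || dm <= 0)
      stop("inhibition variant requires a positive d_max")
    growth <- growth * (1 - d$values / dm)
    kill <- if (keep_kill) p$d_r_day * nv * d$values else 0
  } else {
    kill <- p$d_r_day * nv * d$values
  }
  rhs <- p$D_n * laplacian(n, bc)$values + growth - kill
  field_like(n, rhs, unit = "1/day")
}

#' Right-hand side of the vessel-density equation
#'
#' `dm/dt = D_m lap(m) + m (alpha + beta m + gamma m^2)
#'  + beta_nm div(m grad n) + alpha_nm n (1 - n/n_lim) m - A_r m A`.
#' The cubic is bistable with stable states m = 0 (avascular) and m = 1
#' (vascularized), producing islands of vessels; the two coupling terms model
#' tumor-induced angiogenesis (production at the hypoxic rim, regression in
#' the crowded core) and vessel movement up the tumor-density gradient. The
#' antiangiogenic agent A eliminates vessels at rate A_r.
#'
#' @param m,n,A Vessel, tumor and agent `an_field`s on one grid.
#' @param p An `an_growth_params`.
#' @param bc Boundary condition for the spatial operators.
#' @return An `an_field`, units 1/day.
#' @export
vessel_rhs <- function(m, n, A, p, bc = bc_no_flux()) {
  check_same_grid(m, n, A)
  mv <- m$values; nv <- n$values
  cubic <- mv * (p$alpha + p$beta * mv + p$gamma * mv^2)
  angio <- p$alpha_nm * nv * (1 - nv / p$n_lim) * mv
  chemotax <- p$beta_nm * div_coef_grad(m, n, bc)$values
  rhs <- p$D_m * laplacian(m, bc)$values + cubic + chemotax + angio -
    p$A_r_day * mv * A$values
  field_like(m, rhs, unit = "1/day")
}

#' Maximum stable time step for the explicit growth update
#'
#' Diffusive bound `h^2 / (4 max(D_n, D_m))` for the forward-Euler scheme.
#' Reaction stiffness (drug kill, vessel cubic) can demand a smaller step;
#' the simulation loop keeps dt well below both.
#'
#' @param grid An `an_grid`.
#' @param p An `an_growth_params`.
#' @return Maximum dt in days.
#' @export
max_stable_dt <- function(grid, p) {
  grid$h^2 / (4 * max(p$D_n, p$D_m))
}

#' One explicit time step of the growth system
#'
#' Forward-Euler update of tumor and vessel densities under the current drug
#' fields; negative values produced by the update are clamped to zero
#' (positivity of densities), with a message when
#' `getOption("angionorm.verbose")` is set.
#'
#' @param state List with `an_field`s `n` and `m`.
#' @param drugs List with `an_field`s `A` and `d` (tissue concentrations).
#' @param p An `an_growth_params`.
#' @param dt Time step, days; must satisfy [max_stable_dt()].
#' @param ... Passed to [tumor_rhs()] (e.g. `inhibition_variant`).
#' @return Updated `list(n, m)`.
#' @export
step_growth <- function(state, drugs, p, dt, ...) {
  dt_max <- max_stable_dt(state$n$grid, p)
  if (dt > dt_max)
    stop(sprintf(paste0("dt = %g days violates the diffusive stability ",
                        "bound; use dt <= %g"), dt, dt_max))
  if (dt == 0) return(state)
  dn <- tumor_rhs(state$n, state$m, drugs$d, p, ...)
  dm <- vessel_rhs(state$m, state$n, drugs$A, p)
  nv <- state$n$values + dt * dn$values
  mv <- state$m$values + dt * dm$values
  ncl <- sum(nv < 0); mcl <- sum(mv < 0)
  if ((ncl + mcl) > 0L) {
    if (isTRUE(getOption("angionorm.verbose")))
      message("step_growth: clamped ", ncl, " n-nodes and ", mcl,
              " m-nodes to zero")
    nv[nv < 0] <- 0
    mv[mv < 0] <- 0
  }
  list(n = field_like(state$n, nv), m = field_like(state$m, mv))
}

#' Gaussian initial tumor
#'
#' `n(x) = peak exp(-|x - center|^2 / (2 sigma^2))` with `sigma` chosen so
#' that the `n > 0.1 peak` contour sits at radius `radius0` (the conventional
#' tumor-edge threshold used by all masks in the package).
#'
#' @param grid An `an_grid`.
#' @param center Tumor centre, cm; default is the domain centre.
#' @param radius0 Initial tumor radius, cm (paper-scale default 0.02 cm).
#' @param peak Peak density (dimensionless).
#' @return An `an_field`.
#' @export
init_tumor_gaussian <- function(grid, center = NULL, radius0 = 0.02,
                                peak = 1) {
  if (radius0 <= 0) stop("radius0 must be positive")
  ext <- grid_extent(grid)
  if (radius0 > min(ext) / 2)
    stop("radius0 = ", radius0, " cm exceeds half the domain extent")
  if (is.null(center))
    center <- grid$origin + ext / 2
  sigma2 <- radius0^2 / (2 * log(10))  # n(radius0) = 0.1 * peak
  co <- grid_coords(grid)
  r2 <- (co$x - center[1])^2 + (co$y - center[2])^2
  scalar_field(grid, peak * exp(-r2 / (2 * sigma2)), unit = "dimensionless")
}

#' Random vessel islands
#'
#' Draws i.i.d. uniform(0,1) node values from `seed` and relaxes them under
#' the vessel dynamics alone (no tumor, no agent) for `relax_time` days. The
#' bistable cubic carves the noise into islands near m = 1 and voids near
#' m = 0, emulating the patchy pre-existing vasculature the tumor grows into.
#' Deterministic given the seed.
#'
#' @param grid An `an_grid`.
#' @param seed Integer seed.
#' @param p An `an_growth_params`.
#' @param relax_time Relaxation time, days (default 240; the island cubic
#'   relaxes at a few hundredths per day, so a couple of hundred days are
#'   needed for nodes to settle onto the stable states).
#' @param dt Relaxation time step, days (bounded by the vessel diffusive
#'   stability limit only; tumor diffusivity plays no role here).
#' @return An `an_field` of vessel density.
#' @export
init_vessel_islands <- function(grid, seed, p = growth_params(),
                                relax_time = 240, dt = 0.25) {
  if (relax_time < 0) stop("relax_time must be nonnegative")
  rng <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                       .GlobalEnv) else NULL
    set.seed(as.integer(seed))
    u <- stats::runif(grid$nx * grid$ny)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    u
  })
  m <- scalar_field(grid, matrix(rng, grid$nx, grid$ny))
  if (relax_time == 0) return(m)
  zero <- scalar_field(grid, 0)
  dt <- min(dt, grid$h^2 / (4 * max(p$D_m, 1e-300)))
  t <- 0
  while (t < relax_time - 1e-12) {
    step <- min(dt, relax_time - t)
    dm <- vessel_rhs(m, zero, zero, p)
    mv <- m$values + step * dm$values
    mv[mv < 0] <- 0
    m <- field_like(m, mv)
    t <- t + step
  }
  m
}
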