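#' Dynamic effective conductivity fields
#'
#' Implements the normalization switch. Vessels at density m <= 1 are
#' inherent/normalized vessels with normal-tissue wall properties; density
#' above 1 signals angiogenic, leaky vessels, whose wall conductivity and
#' surface density take tumor values. The switch is a linear ramp on `m` in
#' `(1, 1 + delta)` to keep the elliptic coefficients continuous.
#'
#' The Starling osmotic term follows the tissue, not the wall state: the
#' near-zero oncotic gradient of tumors reflects plasma proteins that have
#' leaked into the interstitium, and it does not recover on the time scale of
#' a normalization pulse. It therefore ramps with tumor density `n` on
#' `(0, n_tum)`. Lymphatics are suppressed the same way: `lambda_l` fades
#' linearly with `n` and vanishes for `n >= n_tum` (the whole-tumor mask
#' threshold).
#'
#' `lambda_b` is the per-unit-vessel-density exchange coefficient
#' `L_p * SV`; the local vessel presence enters separately through the factor
#' `m` in the Starling source.
#'
#' @param n,m Tumor and vessel `an_field`s (nonnegative).
#' @param fp An `an_fluid_params`.
#' @param delta Ramp width above m = 1.
#' @param n_tum Tumor-density threshold extinguishing lymphatics.
#' @return An object of class `an_conductivities`: fields `lambda_b`,
#'   `lambda_l`, `osmotic` (`an_field`s) and `ramp_w` (the leakiness weight
#'   in `[0, 1]`, reused for agent-permeability switching).
#' @export
effective_conductivities <- function(n, m, fp, delta = 0.1, n_tum = 0.1) {
  check_same_grid(n, m)
  if (any(n$values < 0) || any(m$values < 0))
    stop("n and m must be nonnegative")
  w <- pmin(pmax((m$values - 1) / delta, 0), 1)
  lb <- (1 - w) * fp$lambda_b_normal + w * fp$lambda_b_tumor
  wt <- pmin(pmax(n$values / n_tum, 0), 1)
  osm <- (1 - wt) * fp$osmotic_normal + wt * fp$osmotic_tumor
  ll <- fp$lambda_l_normal * pmax(1 - n$values / n_tum, 0)
  structure(list(
    lambda_b = scalar_field(n$grid, lb, unit = "1/mmHg.s"),
    lambda_l = scalar_field(n$grid, ll, unit = "1/mmHg.s"),
    osmotic = scalar_field(n$grid, osm, unit = "mmHg"),
    ramp_w = scalar_field(n$grid, w, unit = "dimensionless"),
    delta = delta, n_tum = n_tum
  ), class = "an_conductivities")
}

#' Starling transvascular fluid source
#'
#' `Gamma_b = lambda_b m (P_v - P - sigma_v(pi_c - pi_i))` in 1/s. Negative
#' where interstitial pressure exceeds the effective microvascular pressure
#' (fluid resorption into vessels).
#'
#' @param m Vessel density `an_field`.
#' @param P Interstitial pressure `an_field`, mmHg.
#' @param cf An `an_conductivities`.
#' @param fp An `an_fluid_params`.
#' @return An `an_field`, 1/s.
#' @export
starling_source <- function(m, P, cf, fp) {
  check_same_grid(m, P, cf$lambda_b)
  g <- cf$lambda_b$values * m$values *
    (fp$P_v - P$values - cf$osmotic$values)
  scalar_field(m$grid, g, unit = "1/s")
}

#' Lymphatic drainage sink
#'
#' `Gamma_l = lambda_l P` in 1/s; lymphatic pressure is fixed at 0 mmHg.
#'
#' @param P Interstitial pressure `an_field`, mmHg.
#' @param cf An `an_conductivities`.
#' @return An `an_field`, 1/s.
#' @export
lymph_sink <- function(P, cf) {
  check_same_grid(P, cf$lambda_l)
  scalar_field(P$grid, cf$lambda_l$values * P$values, unit = "1/s")
}

## Assemble the sparse operator for -Dcoef * lap(u) + diag(react) u on grid g.
## bc_kind "dirichlet": boundary nodes become identity rows (caller fixes rhs);
## "no_flux": mirror closure folded into the stencil (pure Neumann).
## Returns a dgCMatrix; node ordering k = i + (j-1)*nx.
assemble_reaction_diffusion <- function(g, Dcoef, react, bc_kind) {
  nx <- g$nx; ny <- g$ny; h <- g$h
  N <- nx * ny
  ii <- rep(seq_len(nx), ny)
  jj <- rep(seq_len(ny), each = nx)
  k <- seq_len(N)
  s <- Dcoef / h^2
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  add <- function(r, c, v) {
    rows <<- c(rows, r); cols <<- c(cols, c); vals <<- c(vals, v)
  }
  if (bc_kind == "no_flux") {
    # conservative closure: a boundary face simply carries no flux, so the
    # missing neighbour drops out of both the off-diagonal and the diagonal
    hw <- ii > 1L; he <- ii < nx; hs <- jj > 1L; hn <- jj < ny
    add(k[hw], (ii - 1L + (jj - 1L) * nx)[hw], rep(-s, sum(hw)))
    add(k[he], (ii + 1L + (jj - 1L) * nx)[he], rep(-s, sum(he)))
    add(k[hs], (ii + (jj - 2L) * nx)[hs], rep(-s, sum(hs)))
    add(k[hn], (ii + jj * nx)[hn], rep(-s, sum(hn)))
    add(k, k, (hw + he + hs + hn) * s + as.vector(react))
  } else {
    interior <- ii > 1L & ii < nx & jj > 1L & jj < ny
    ki <- k[interior]
    add(ki, ki - 1L, rep(-s, length(ki)))
    add(ki, ki + 1L, rep(-s, length(ki)))
    add(ki, ki - nx, rep(-s, length(ki)))
    add(ki, ki + nx, rep(-s, length(ki)))
    add(ki, ki, 4 * s + as.vector(react)[interior])
    kb <- k[!interior]
    add(kb, kb, rep(1, length(kb)))
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(N, N))
}

boundary_mask <- function(g) {
  m <- matrix(FALSE, g$nx, g$ny)
  m[1, ] <- TRUE; m[g$nx, ] <- TRUE; m[, 1] <- TRUE; m[, g$ny] <- TRUE
  m
}

#' Solve the interstitial fluid pressure equation
#'
#' Steady Darcy/Starling balance
#' `-K lap(P) = lambda_b m (P_v - P - osmotic) - lambda_l P`, assembled as a
#' sparse 5-point system and solved directly. The default boundary condition
#' is Dirichlet at the healthy-tissue equilibrium pressure
#' ([normal_equilibrium_pressure()], about 0.022 mmHg), so that pressure
#' relaxes to its normal value in host tissue; pass `bc = bc_dirichlet(v)`
#' for any other far-field value or `bc_no_flux()` for a sealed domain.
#'
#' @param m Vessel density `an_field`.
#' @param cf An `an_conductivities` (from [effective_conductivities()] or a
#'   fixture).
#' @param fp An `an_fluid_params`.
#' @param bc An `an_bc`; `NULL` selects the default far-field Dirichlet.
#' @return Pressure `an_field`, mmHg; relative residual is checked to 1e-10.
#' @export
solve_ifp <- function(m, cf, fp, bc = NULL) {
  check_same_grid(m, cf$lambda_b)
  g <- m$grid
  if (is.null(bc)) bc <- bc_dirichlet(normal_equilibrium_pressure(fp))
  react <- cf$lambda_b$values * m$values + cf$lambda_l$values
  if (any(react < 0)) stop("reaction coefficients must be nonnegative")
  rhs <- cf$lambda_b$values * m$values * (fp$P_v - cf$osmotic$values)
  if (bc$kind == "no_flux" && all(react == 0))
    stop("pure no-flux problem with all exchange coefficients zero is ",
         "singular: pressure is defined only up to a constant")
  A <- assemble_reaction_diffusion(g, fp$K, react, bc$kind)
  b <- as.vector(rhs)
  if (bc$kind == "dirichlet") b[as.vector(boundary_mask(g))] <- bc$value
  sol <- as.vector(Matrix::solve(A, b))
  res <- sqrt(sum((as.vector(A %*% sol) - b)^2))
  nb <- sqrt(sum(b^2))
  if (nb > 0 && res > 1e-10 * nb)
    stop("IFP solve failed: relative residual ", res / nb)
  scalar_field(g, matrix(sol, g$nx, g$ny), unit = "mmHg")
}

#' Analytic radial IFP oracle
#'
#' Closed-form solution of the radially symmetric pressure equation for a
#' disc tumor of radius `R` with uniform leaky-wall coefficients inside (no
#' lymphatics) and normal-tissue coefficients outside, built from modified
#' Bessel functions `I0`/`K0` with continuity of pressure and flux at the
#' interface and decay to the healthy equilibrium far away. Vessel density is
#' `m = 1` everywhere. Serves as an independent oracle for [solve_ifp()].
#'
#' @param R Tumor radius, cm.
#' @param fp An `an_fluid_params`.
#' @param r_values Radii at which to evaluate, cm (nonnegative).
#' @return Numeric vector of pressures, mmHg.
#' @export
analytic_ifp_radial <- function(R, fp, r_values) {
  if (R <= 0) stop("tumor radius R must be positive")
  if (any(r_values < 0)) stop("radii must be nonnegative")
  qt <- sqrt(fp$lambda_b_tumor / fp$K)
  qn <- sqrt((fp$lambda_b_normal + fp$lambda_l_normal) / fp$K)
  P_inf <- normal_equilibrium_pressure(fp)
  Pt <- fp$P_eff_tumor
  # P_in  = Pt    + a * I0(qt r)/I0(qt R)
  # P_out = P_inf + b * K0(qn r)/K0(qn R)
  # continuity: a - b = P_inf - Pt ; flux: a A1 + b B1 = 0
  i0R <- besselI(qt * R, 0, expon.scaled = TRUE)
  i1R <- besselI(qt * R, 1, expon.scaled = TRUE)
  k0R <- besselK(qn * R, 0, expon.scaled = TRUE)
  k1R <- besselK(qn * R, 1, expon.scaled = TRUE)
  A1 <- qt * i1R / i0R
  B1 <- qn * k1R / k0R
  a <- (P_inf - Pt) * B1 / (A1 + B1)
  b <- -a * A1 / B1
  out <- numeric(length(r_values))
  inside <- r_values <= R
  ri <- r_values[inside]
  out[inside] <- Pt + a *
    (besselI(qt * ri, 0, expon.scaled = TRUE) / i0R) * exp(qt * (ri - R))
  ro <- r_values[!inside]
  out[!inside] <- P_inf + b *
    (besselK(qn * ro, 0, expon.scaled = TRUE) / k0R) * exp(-qn * (ro - R))
  out
}

#' Darcy interstitial fluid velocity
#'
#' `u = -K grad(P)`, cm/s.
#'
#' @param P Pressure `an_field`, mmHg.
#' @param fp An `an_fluid_params`.
#' @param bc Boundary condition for the gradient (default mirror).
#' @return List of `an_field`s `ux`, `uy` in cm/s.
#' @export
darcy_velocity <- function(P, fp, bc = bc_no_flux()) {
  gr <- gradient(P, bc)
  list(ux = field_like(P, -fp$K * gr$dx$values, unit = "cm/s"),
       uy = field_like(P, -fp$K * gr$dy$values, unit = "cm/s"))
}
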