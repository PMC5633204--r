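#' Bolus dose event
#'
#' @param day Simulation day of administration (>= 0).
#' @param kind `"antiangiogenic"` or `"chemo"`.
#' @param peak Dimensionless peak plasma concentration added by the bolus.
#' @return An object of class `an_dose_event`.
#' @export
dose_event <- function(day, kind = c("antiangiogenic", "chemo"), peak) {
  kind <- match.arg(kind)
  if (day < 0) stop("dose day must be nonnegative")
  if (peak < 0) stop("dose peak must be nonnegative")
  structure(list(day = day, kind = kind, peak = peak),
            class = "an_dose_event")
}

#' Plasma concentration from bolus events
#'
#' Each bolus decays exponentially, `peak * exp(-(t - t_event)/tau)`, and
#' repeat doses superpose (linear pharmacokinetics). `tau` is the plasma time
#' constant as tabulated: the concentration falls to `1/e` of the peak after
#' `tau` hours. Set `halflife_ln2 = TRUE` to reinterpret `tau` as a true
#' half-life (decay `exp(-t ln 2 / tau)`).
#'
#' @param t Time in hours (vectorized).
#' @param events List of `an_dose_event`s (their `day` converted at 24 h/day).
#' @param time_constant Plasma time constant, hours.
#' @param halflife_ln2 Logical; see above.
#' @return Dimensionless plasma concentration, zero before the first event.
#' @export
plasma_concentration <- function(t, events, time_constant,
                                 halflife_ln2 = FALSE) {
  if (time_constant <= 0) stop("time constant must be positive")
  rate <- if (halflife_ln2) log(2) / time_constant else 1 / time_constant
  out <- numeric(length(t))
  for (ev in events) {
    t0 <- ev$day * 24
    act <- t >= t0
    out[act] <- out[act] + ev$peak * exp(-(t[act] - t0) * rate)
  }
  out
}

## switched transvascular agent permeability on the leakiness ramp
agent_permeability <- function(cf, ap) {
  (1 - cf$ramp_w$values) * ap$lambda_A_normal +
    cf$ramp_w$values * ap$lambda_A_tumor
}

#' Quasi-steady antiangiogenic agent field
#'
#' Solves `0 = D_A lap(A) + lambda_A m (A_v - A) - Gamma_l A - k_A A` with
#' no-flux boundaries. The agent is a small molecule: it enters tissue by
#' transvascular diffusion (permeability switching tumor/normal on the same
#' leakiness ramp as the wall conductivity), drains into lymphatics at the
#' local fluid drainage rate and decays.
#'
#' @param A_v Plasma agent concentration (dimensionless scalar, >= 0).
#' @param m,n Vessel and tumor `an_field`s.
#' @param cf An `an_conductivities`.
#' @param ap An `an_agent_params`.
#' @param P Pressure `an_field` (for the lymphatic drainage rate); `NULL`
#'   means no drainage.
#' @param bc Must be no-flux.
#' @return Agent `an_field` (dimensionless), nonnegative.
#' @export
solve_agent <- function(A_v, m, n, cf, ap, P = NULL, bc = bc_no_flux()) {
  if (A_v < 0) stop("plasma concentration A_v must be nonnegative")
  if (bc$kind != "no_flux")
    stop("the agent transport problem uses no-flux boundaries")
  check_same_grid(m, n, cf$lambda_b)
  g <- m$grid
  if (A_v == 0) return(scalar_field(g, 0, unit = "concentration"))
  lamA <- agent_permeability(cf, ap)
  drain <- if (is.null(P)) 0 else cf$lambda_l$values * P$values
  react <- lamA * m$values + drain + ap$k_A
  M <- assemble_reaction_diffusion(g, ap$D_A, react, "no_flux")
  b <- as.vector(lamA * m$values * A_v)
  sol <- as.vector(Matrix::solve(M, b))
  res <- sqrt(sum((as.vector(M %*% sol) - b)^2)) / max(sqrt(sum(b^2)), 1e-300)
  if (res > 1e-10) stop("agent solve failed: relative residual ", res)
  sol[sol < 0] <- 0
  scalar_field(g, matrix(sol, g$nx, g$ny), unit = "concentration")
}

## Upwind convection operator for velocity u = -k_E K grad(P):
## adds the matrix of +div(u d) with first-order upwinding and sealed
## boundary faces. Returns a sparse matrix to add to the system.
assemble_upwind_convection <- function(g, P, kEK) {
  nx <- g$nx; ny <- g$ny; h <- g$h
  N <- nx * ny
  Pv <- P$values
  # face velocities (cm/s); ue[i,j] on the face between (i,j) and (i+1,j)
  ue <- -kEK * (Pv[2:nx, , drop = FALSE] - Pv[1:(nx - 1), , drop = FALSE]) / h
  un <- -kEK * (Pv[, 2:ny, drop = FALSE] - Pv[, 1:(ny - 1), drop = FALSE]) / h
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  add <- function(r, c, v) {
    keep <- v != 0
    rows <<- c(rows, r[keep]); cols <<- c(cols, c[keep])
    vals <<- c(vals, v[keep])
  }
  idx <- function(i, j) i + (j - 1L) * nx
  # x-faces: flux F = u * d_upwind, contributes +F/h to left node row,
  # -F/h to right node row
  iL <- as.vector(row(ue)); jL <- as.vector(col(ue))
  kL <- idx(iL, jL); kR <- idx(iL + 1L, jL)
  u <- as.vector(ue)
  up <- pmax(u, 0); um <- pmin(u, 0)  # upwind splits
  # left row: +(up*dL + um*dR)/h ; right row: -(up*dL + um*dR)/h
  add(kL, kL, up / h); add(kL, kR, um / h)
  add(kR, kL, -up / h); add(kR, kR, -um / h)
  # y-faces
  iB <- as.vector(row(un)); jB <- as.vector(col(un))
  kB <- idx(iB, jB); kT <- idx(iB, jB + 1L)
  u <- as.vector(un)
  up <- pmax(u, 0); um <- pmin(u, 0)
  add(kB, kB, up / h); add(kB, kT, um / h)
  add(kT, kB, -up / h); add(kT, kT, -um / h)
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(N, N))
}

#' Quasi-steady liposomal drug field
#'
#' Solves the convection-diffusion balance
#' `0 = D_d lap(d) + div(k_E d K grad P) + Gamma_b^+ (1 - sigma_d) d_v
#'  - Gamma_l d - d_r n d - k_d d`
#' with no-flux boundaries. Liposomes extravasate by convective solvent drag
#' only (`Gamma_b^+ = max(Gamma_b, 0)`: no convective re-entry where fluid is
#' resorbed), ride the retarded Darcy flow through the interstitium, drain
#' into lymphatics, are consumed by tumor cells and decay. The upwind
#' discretization yields an M-matrix, so the solution is nonnegative.
#'
#' @param d_v Plasma drug concentration (dimensionless scalar, >= 0).
#' @param m,n Vessel and tumor `an_field`s.
#' @param P Solved pressure `an_field`, mmHg.
#' @param cf An `an_conductivities`.
#' @param lp An `an_liposome_params`.
#' @param gp An `an_growth_params` (for the consumption rate `d_r`).
#' @param fp An `an_fluid_params`.
#' @param bc Must be no-flux.
#' @return Drug `an_field` (dimensionless tissue concentration).
#' @export
solve_liposome <- function(d_v, m, n, P, cf, lp, gp, fp, bc = bc_no_flux()) {
  if (d_v < 0) stop("plasma concentration d_v must be nonnegative")
  if (bc$kind != "no_flux")
    stop("the liposome transport problem uses no-flux boundaries")
  check_same_grid(m, n, P, cf$lambda_b)
  g <- m$grid
  if (d_v == 0) return(scalar_field(g, 0, unit = "concentration"))
  gb <- starling_source(m, P, cf, fp)$values
  src <- pmax(gb, 0) * (1 - lp$sigma_d) * d_v
  drain <- cf$lambda_l$values * P$values
  react <- drain + (gp$d_r / 3600) * n$values + lp$k_d
  M <- assemble_reaction_diffusion(g, lp$D_d, react, "no_flux") +
    assemble_upwind_convection(g, P, lp$k_E * fp$K)
  b <- as.vector(src)
  sol <- as.vector(Matrix::solve(M, b))
  res <- sqrt(sum((as.vector(M %*% sol) - b)^2)) / max(sqrt(sum(b^2)), 1e-300)
  if (res > 1e-8) stop("liposome solve failed: relative residual ", res)
  sol[sol < 0] <- 0
  scalar_field(g, matrix(sol, g$nx, g$ny), unit = "concentration")
}

#' Convective extravasation coefficient
#'
#' `Gamma_b (1 - sigma_d)` in 1/s: the transvascular convective extravasation
#' rate of liposomes per unit plasma concentration. The central diagnostic of
#' normalization benefit: antiangiogenic therapy lowers IFP, restoring the
#' transvascular pressure difference in `Gamma_b`.
#'
#' @param m Vessel density `an_field`.
#' @param P Pressure `an_field`.
#' @param cf An `an_conductivities`.
#' @param lp An `an_liposome_params`.
#' @param fp An `an_fluid_params`.
#' @param clamp Logical; clamp to the one-way (extravasation-only) part
#'   `max(Gamma_b, 0)` as used by the drug source (default FALSE reports the
#'   signed coefficient).
#' @return An `an_field`, 1/s.
#' @export
extravasation_coefficient <- function(m, P, cf, lp, fp, clamp = FALSE) {
  gb <- starling_source(m, P, cf, fp)$values
  if (clamp) gb <- pmax(gb, 0)
  scalar_field(m$grid, gb * (1 - lp$sigma_d), unit = "1/s")
}
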