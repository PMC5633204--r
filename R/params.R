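#' Growth-dynamics parameters
#'
#' Rates for the coupled tumor-cell / vessel-density reaction-diffusion
#' system. The vessel-island cubic `m (alpha + beta m + gamma m^2)` must have
#' `alpha + beta + gamma = 0` so that `m = 1` is a fixed point, and `m = 0`
#' and `m = 1` must both be stable (the middle root is the basin boundary).
#'
#' Time unit for integration is days. The two drug-action rates `d_r` and
#' `A_r` are specified per hour (as customarily tabulated) and converted
#' internally; the converted per-day values are available as `d_r_day` and
#' `A_r_day`.
#'
#' @param D_n Tumor cell diffusivity, cm^2/day.
#' @param r Logistic growth rate, 1/day.
#' @param n_lim Carrying capacity (dimensionless density scale).
#' @param alpha_mn Vessel-assisted proliferation rate, 1/day per unit m.
#' @param d_r Chemotherapy kill rate, 1/hour.
#' @param D_m Vessel diffusivity, cm^2/day.
#' @param alpha,beta,gamma Vessel-island cubic coefficients, 1/day.
#' @param beta_nm_hat Vessel chemotaxis-like coefficient, dimensionless (as
#'   customarily printed; lengths measured in units of the reference front
#'   width `beta_nm_length`).
#' @param beta_nm_length Reference length for `beta_nm_hat`, cm: the natural
#'   front width `sqrt(D_n/r)` of the default tumor wave (a fixed model
#'   constant, not recomputed on calibration). The dimensional coefficient
#'   used in the equations is `beta_nm = beta_nm_hat * beta_nm_length^2`
#'   (cm^2/day), exposed as a derived field.
#' @param alpha_nm Angiogenesis production rate, 1/day.
#' @param A_r Antiangiogenic kill rate, 1/hour.
#' @param d_max Scale for the growth-inhibition drug variant (dimensionless);
#'   `NA` means "track the running maximum of extravasated drug".
#' @return An object of class `an_growth_params`.
#' @export
growth_params <- function(D_n = 1.6e-3, r = 0.3, n_lim = 1,
                          alpha_mn = 0.02, d_r = 1,
                          D_m = 1e-5,
                          alpha = -0.0375, beta = 0.15, gamma = -0.1125,
                          beta_nm_hat = 0.5,
                          beta_nm_length = sqrt(1.6e-3 / 0.3),
                          alpha_nm = 0.25,
                          A_r = 1, d_max = NA_real_) {
  if (is.null(d_max) || length(d_max) == 0) d_max <- NA_real_
  p <- list(D_n = D_n, r = r, n_lim = n_lim, alpha_mn = alpha_mn,
            d_r = d_r, D_m = D_m,
            alpha = alpha, beta = beta, gamma = gamma,
            beta_nm_hat = beta_nm_hat, beta_nm_length = beta_nm_length,
            alpha_nm = alpha_nm,
            A_r = A_r, d_max = d_max)
  if (p$n_lim <= 0) stop("n_lim must be positive")
  if (p$r < 0) stop("growth rate r must be nonnegative")
  if (p$D_n < 0 || p$D_m < 0) stop("diffusivities must be nonnegative")
  if (abs(p$alpha + p$beta + p$gamma) > 1e-12)
    stop("vessel cubic must satisfy alpha + beta + gamma = 0 ",
         "(so m = 1 is a fixed point); got sum = ",
         p$alpha + p$beta + p$gamma)
  if (p$alpha >= 0)
    stop("alpha must be negative so m = 0 is stable")
  ## stability of m = 1: f'(1) = alpha + 2 beta + 3 gamma < 0
  if (p$alpha + 2 * p$beta + 3 * p$gamma >= 0)
    stop("m = 1 must be a stable root of the vessel cubic: ",
         "alpha + 2*beta + 3*gamma must be negative")
  ## real middle root between 0 and 1 (basin boundary)
  disc <- p$beta^2 - 4 * p$alpha * p$gamma
  if (disc <= 0)
    stop("vessel cubic has no real interior root; m = 0 and m = 1 ",
         "are not separated by an unstable point")
  if (p$beta_nm_length <= 0) stop("beta_nm_length must be positive")
  p$beta_nm <- p$beta_nm_hat * p$beta_nm_length^2
  p$d_r_day <- p$d_r * 24
  p$A_r_day <- p$A_r * 24
  structure(p, class = "an_growth_params")
}

#' Interstitial fluid transport parameters
#'
#' Tumor/normal values for wall conductivity, vessel surface density,
#' lymphatic conductivity and the Starling osmotic term. The blood-side
#' exchange coefficient is always derived as `lambda_b = L_p * SV`, and the
#' effective microvascular pressure as `P_eff = P_v - sigma_v (pi_c - pi_i)`;
#' neither is ever entered by hand.
#'
#' @param K Interstitial hydraulic conductivity, cm^2/(mmHg s).
#' @param L_p_normal,L_p_tumor Vessel-wall hydraulic conductivity,
#'   cm/(mmHg s).
#' @param SV_normal,SV_tumor Vessel surface area per tissue volume,
#'   cm^2/cm^3.
#' @param lambda_l_normal Lymphatic conductivity, 1/(mmHg s).
#' @param P_v Microvascular (vascular) pressure, mmHg.
#' @param osmotic_normal,osmotic_tumor Combined osmotic reflection term
#'   `sigma_v (pi_c - pi_i)`, mmHg.
#' @param lymph_pressure Pressure inside lymphatics, mmHg (0 by convention).
#' @return An object of class `an_fluid_params`; derived fields
#'   `lambda_b_tumor`, `lambda_b_normal`, `P_eff_tumor`, `P_eff_normal`.
#' @export
fluid_params <- function(K = 2.5e-7,
                         L_p_normal = 3.6e-8, L_p_tumor = 1.86e-6,
                         SV_normal = 70, SV_tumor = 200,
                         lambda_l_normal = 6.66e-4,
                         P_v = 15,
                         osmotic_normal = 9.1, osmotic_tumor = 2.2e-4,
                         lymph_pressure = 0) {
  p <- list(K = K, L_p_normal = L_p_normal, L_p_tumor = L_p_tumor,
            SV_normal = SV_normal, SV_tumor = SV_tumor,
            lambda_l_normal = lambda_l_normal, P_v = P_v,
            osmotic_normal = osmotic_normal, osmotic_tumor = osmotic_tumor,
            lymph_pressure = lymph_pressure)
  conds <- c(p$K, p$L_p_normal, p$L_p_tumor, p$SV_normal, p$SV_tumor,
             p$lambda_l_normal)
  if (any(conds < 0)) stop("conductivities and surface densities must be >= 0")
  p$lambda_b_tumor <- p$L_p_tumor * p$SV_tumor
  p$lambda_b_normal <- p$L_p_normal * p$SV_normal
  p$P_eff_tumor <- p$P_v - p$osmotic_tumor
  p$P_eff_normal <- p$P_v - p$osmotic_normal
  structure(p, class = "an_fluid_params")
}

#' Normal-tissue equilibrium interstitial pressure
#'
#' The spatially uniform Starling balance of healthy tissue with `m = 1`:
#' `lambda_b,n (P_eff,n - P) = lambda_l,n P`, giving
#' `P = lambda_b,n P_eff,n / (lambda_b,n + lambda_l,n)` (about 0.022 mmHg for
#' the default parameters). Used as the default far-field Dirichlet pressure.
#'
#' @param fp An `an_fluid_params`.
#' @return Pressure in mmHg.
#' @export
normal_equilibrium_pressure <- function(fp) {
  fp$lambda_b_normal * fp$P_eff_normal /
    (fp$lambda_b_normal + fp$lambda_l_normal)
}

#' Antiangiogenic agent transport parameters
#'
#' @param D_A Tissue diffusivity, cm^2/s.
#' @param lambda_A_tumor,lambda_A_normal Transvascular diffusion coefficient
#'   per unit vessel density, 1/s.
#' @param k_A First-order decay rate, 1/s.
#' @param t_half_A Plasma decay time constant, hours.
#' @return An object of class `an_agent_params`.
#' @export
agent_params <- function(D_A = 4e-7,
                         lambda_A_tumor = 4e-6, lambda_A_normal = 1.4e-7,
                         k_A = 1.65e-6, t_half_A = 20) {
  p <- list(D_A = D_A, lambda_A_tumor = lambda_A_tumor,
            lambda_A_normal = lambda_A_normal, k_A = k_A,
            t_half_A = t_half_A)
  if (any(unlist(p) < 0)) stop("agent parameters must be nonnegative")
  structure(p, class = "an_agent_params")
}

#' Pore-exclusion reflection coefficient
#'
#' Solvent-drag reflection coefficient of a spherical particle in a
#' cylindrical pore: `sigma_d = (1 - (1 - a)^2)^2` with `a` the ratio of
#' particle to pore radius. `1 - sigma_d` is the transmitted fraction carried
#' by transvascular convection.
#'
#' @param drug_radius Particle radius, nm.
#' @param pore_radius Pore radius, nm (must be >= drug_radius).
#' @return `sigma_d`, dimensionless in `[0, 1]`.
#' @examples
#' 1 - reflection_coefficient(100, 500)  # 0.8704, ~0.87
#' @export
reflection_coefficient <- function(drug_radius, pore_radius) {
  if (drug_radius < 0 || pore_radius <= 0)
    stop("radii must be positive")
  if (drug_radius > pore_radius)
    stop("drug radius exceeds pore radius: the particle cannot pass")
  a <- drug_radius / pore_radius
  (1 - (1 - a)^2)^2
}

#' Liposomal drug transport parameters
#'
#' The reflection coefficient `sigma_d` is derived from the pore-exclusion
#' formula and never entered by hand. Transvascular diffusion of liposomes is
#' neglected (convection-dominated); the diffusional permeability `P_d` and
#' the tabulated `lambda_d` are recorded for provenance but unused.
#'
#' @param D_d Tissue diffusivity, cm^2/s.
#' @param k_E Interstitial convective retardation coefficient (0..1).
#' @param k_d First-order decay rate, 1/s.
#' @param t_half_d Plasma decay time constant, hours.
#' @param drug_radius,pore_radius Radii for the pore model, nm.
#' @param P_d Diffusional wall permeability, cm/s (recorded, unused).
#' @param lambda_d Tabulated transvascular diffusion coefficient, 1/s
#'   (recorded, unused).
#' @return An object of class `an_liposome_params` with derived `sigma_d`.
#' @export
liposome_params <- function(D_d = 2.5e-9, k_E = 0.35,
                            k_d = 1.65e-6, t_half_d = 45.2,
                            drug_radius = 100, pore_radius = 500,
                            P_d = 0.05 * 3.42e-7, lambda_d = 4e-6) {
  if (k_E < 0 || k_E > 1) stop("k_E must lie in [0, 1]")
  if (D_d < 0 || k_d < 0 || t_half_d <= 0)
    stop("liposome transport parameters out of range")
  sigma_d <- reflection_coefficient(drug_radius, pore_radius)
  structure(list(D_d = D_d, k_E = k_E, sigma_d = sigma_d, k_d = k_d,
                 t_half_d = t_half_d, drug_radius = drug_radius,
                 pore_radius = pore_radius, P_d = P_d, lambda_d = lambda_d),
            class = "an_liposome_params")
}
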