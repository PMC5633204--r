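#' Build a treatment regimen
#'
#' Encodes the four reference schedules: a fixed liposomal chemotherapy dose
#' on days 23/25/27 and antiangiogenic pulses every other day whose peaks
#' taper multiplicatively (pulse k gets `aa_peak * taper_factor^k`).
#'
#' * `case1` — antiangiogenic agent alone, 4 pulses from day 23.
#' * `case2` — chemotherapy alone, days 23/25/27.
#' * `case3` — antiangiogenic lead-in (5 pulses from day 19) + chemotherapy.
#' * `case4` — concurrent (4 antiangiogenic pulses from day 23) +
#'   chemotherapy.
#'
#' @param label One of `"case1"`..`"case4"` or `"custom"`.
#' @param chemo_days Chemotherapy administration days.
#' @param aa_start_day First antiangiogenic day (custom schedules).
#' @param aa_pulses Number of antiangiogenic pulses, 0..6.
#' @param aa_peak Peak plasma concentration of the first antiangiogenic
#'   pulse.
#' @param chemo_peak Peak plasma concentration of each chemotherapy bolus.
#' @param taper_factor Per-pulse multiplicative reduction of antiangiogenic
#'   peaks (<= 1).
#' @return An object of class `an_regimen`: ordered `events`, plus the
#'   construction arguments.
#' @export
build_regimen <- function(label = c("case1", "case2", "case3", "case4",
                                    "custom"),
                          chemo_days = c(23, 25, 27),
                          aa_start_day = 23, aa_pulses = 4,
                          aa_peak = 0.02, chemo_peak = 0.01,
                          taper_factor = 0.8) {
  label <- match.arg(label)
  if (!(aa_pulses %in% 0:6)) stop("aa_pulses must be in 0..6")
  if (taper_factor > 1 || taper_factor < 0)
    stop("taper_factor must lie in [0, 1]")
  spec <- switch(label,
    case1 = list(aa_start = 23, pulses = 4, chemo = numeric(0)),
    case2 = list(aa_start = NA, pulses = 0, chemo = chemo_days),
    case3 = list(aa_start = 19, pulses = 5, chemo = chemo_days),
    case4 = list(aa_start = 23, pulses = 4, chemo = chemo_days),
    custom = list(aa_start = aa_start_day, pulses = aa_pulses,
                  chemo = chemo_days))
  events <- list()
  if (spec$pulses > 0) {
    days <- spec$aa_start + 2 * (seq_len(spec$pulses) - 1)
    for (k in seq_along(days))
      events[[length(events) + 1L]] <-
        dose_event(days[k], "antiangiogenic",
                   aa_peak * taper_factor^(k - 1))
  }
  for (dday in spec$chemo)
    events[[length(events) + 1L]] <- dose_event(dday, "chemo", chemo_peak)
  ord <- order(vapply(events, `[[`, numeric(1), "day"))
  structure(list(events = events[ord], label = label,
                 taper_factor = taper_factor, aa_peak = aa_peak,
                 chemo_peak = chemo_peak),
            class = "an_regimen")
}

#' @export
print.an_regimen <- function(x, ...) {
  cat(sprintf("<an_regimen %s: %d events>\n", x$label, length(x$events)))
  for (ev in x$events)
    cat(sprintf("  day %5.1f  %-15s peak %.4g\n", ev$day, ev$kind, ev$peak))
  invisible(x)
}

#' Rescale the antiangiogenic peaks of a regimen
#'
#' Multiplies every antiangiogenic event peak so that the first pulse peaks
#' at `peak`, preserving the taper profile. Used to apply a calibrated dose.
#'
#' @param regimen An `an_regimen` with antiangiogenic events.
#' @param peak New first-pulse peak plasma concentration.
#' @return The rescaled `an_regimen`.
#' @export
rescale_aa_peak <- function(regimen, peak) {
  kinds <- vapply(regimen$events, `[[`, character(1), "kind")
  old <- regimen$aa_peak
  if (old == 0) stop("regimen has zero antiangiogenic peak; cannot rescale")
  for (i in which(kinds == "antiangiogenic"))
    regimen$events[[i]]$peak <- regimen$events[[i]]$peak * peak / old
  regimen$aa_peak <- peak
  regimen
}

regimen_days <- function(regimen, kind) {
  kinds <- vapply(regimen$events, `[[`, character(1), "kind")
  vapply(regimen$events[kinds == kind], `[[`, numeric(1), "day")
}

#' Simulation configuration
#'
#' Bundles the grid specification, all parameter blocks, the regimen and the
#' numerical controls of the coupled simulation.
#'
#' @param nx,ny Grid node counts.
#' @param extent Domain edge length, cm (square domain).
#' @param gp,fp,ap,lp Parameter blocks ([growth_params()], [fluid_params()],
#'   [agent_params()], [liposome_params()]).
#' @param regimen An `an_regimen` or `NULL` (control growth).
#' @param seed Integer seed driving all randomness (vessel initialization).
#' @param t_end Final simulation day.
#' @param dt Growth time step, days.
#' @param pk_dt PK sampling interval while any drug is in plasma, days.
#' @param metric_dt Metric/pressure sampling interval outside dosing, days.
#' @param snapshot_dt Field snapshot interval, days (`Inf` for none).
#' @param radius0 Initial tumor radius, cm.
#' @param relax_time Vessel-island relaxation time, days.
#' @param inhibition_variant,keep_kill Growth-inhibition drug action flags
#'   (see [tumor_rhs()]).
#' @param halflife_ln2 Interpret plasma time constants as true half-lives.
#' @param boundary_literal Use the vascular pressure `P_v` as the far-field
#'   Dirichlet value instead of the healthy equilibrium pressure.
#' @param interior_threshold,tumor_threshold Mask thresholds on `n`.
#' @return An object of class `an_sim_config`.
#' @export
sim_config <- function(nx = 151, ny = nx, extent = 3,
                       gp = growth_params(), fp = fluid_params(),
                       ap = agent_params(), lp = liposome_params(),
                       regimen = NULL, seed = 1L,
                       t_end = 30, dt = 0.025, pk_dt = 0.05,
                       metric_dt = 0.25, snapshot_dt = Inf,
                       radius0 = 0.02, relax_time = 240,
                       inhibition_variant = FALSE, keep_kill = FALSE,
                       halflife_ln2 = FALSE, boundary_literal = FALSE,
                       interior_threshold = 1, tumor_threshold = 0.1) {
  if (!is.null(regimen)) {
    days <- vapply(regimen$events, `[[`, numeric(1), "day")
    if (length(days) > 0 && t_end <= max(days))
      stop("t_end = ", t_end, " must exceed the last event day (",
           max(days), ")")
  }
  structure(list(nx = as.integer(nx), ny = as.integer(ny), extent = extent,
                 gp = gp, fp = fp, ap = ap, lp = lp, regimen = regimen,
                 seed = as.integer(seed), t_end = t_end, dt = dt,
                 pk_dt = pk_dt, metric_dt = metric_dt,
                 snapshot_dt = snapshot_dt, radius0 = radius0,
                 relax_time = relax_time,
                 inhibition_variant = inhibition_variant,
                 keep_kill = keep_kill, halflife_ln2 = halflife_ln2,
                 boundary_literal = boundary_literal,
                 interior_threshold = interior_threshold,
                 tumor_threshold = tumor_threshold),
            class = "an_sim_config")
}

config_grid <- function(cfg) {
  grid_2d(cfg$nx, cfg$ny, h = cfg$extent / (cfg$nx - 1))
}

## initial state (Gaussian tumor + relaxed vessel islands) for a config
initial_state <- function(cfg) {
  g <- config_grid(cfg)
  list(n = init_tumor_gaussian(g, radius0 = cfg$radius0),
       m = init_vessel_islands(g, seed = cfg$seed, p = cfg$gp,
                               relax_time = cfg$relax_time))
}

ifp_bc <- function(cfg) {
  if (cfg$boundary_literal) bc_dirichlet(cfg$fp$P_v)
  else bc_dirichlet(normal_equilibrium_pressure(cfg$fp))
}

#' Run the coupled tumor / vasculature / IFP / drug simulation
#'
#' Master loop. Each growth step: (1) effective conductivities from the
#' current densities; (2) IFP solve; (3) plasma concentrations from the
#' regimen; (4) quasi-steady agent and liposome solves at the PK sampling
#' cadence (fields held between samples); (5) explicit growth update under
#' the current drug fields; (6) metric accumulation. Pressure and drug
#' solves are skipped while no drug is in plasma (they do not feed back on
#' growth then); pressure is still refreshed at the metric cadence for
#' reporting. Fully deterministic given the config seed.
#'
#' @param cfg An `an_sim_config`.
#' @param init_state Optional `list(n, m)` of `an_field`s to resume from
#'   (defaults to the config's generated initial condition).
#' @param t_start,t_stop Simulated day range (defaults 0..`t_end`).
#' @return An object of class `an_sim_result`: `metrics` (data.frame, one
#'   row per sample time), `snapshots` (named list of field lists),
#'   `state` (final `n`, `m`), `d_running_max`, and the `config`.
#' @export
run_simulation <- function(cfg, init_state = NULL, t_start = 0,
                           t_stop = cfg$t_end) {
  g <- config_grid(cfg)
  state <- if (is.null(init_state)) initial_state(cfg) else init_state
  check_same_grid(state$n, state$m)
  events <- if (is.null(cfg$regimen)) list() else cfg$regimen$events
  kinds <- vapply(events, `[[`, character(1), "kind")
  aa_events <- events[kinds == "antiangiogenic"]
  chemo_events <- events[kinds == "chemo"]
  bcP <- ifp_bc(cfg)
  zero <- scalar_field(g, 0, unit = "concentration")
  A_field <- zero; d_field <- zero
  P_field <- NULL; cf <- NULL
  d_running_max <- if (!is.null(cfg$gp$d_max) && !is.na(cfg$gp$d_max))
    cfg$gp$d_max else 0
  dt <- min(cfg$dt, max_stable_dt(g, cfg$gp))
  n_steps <- ceiling((t_stop - t_start) / dt - 1e-9)
  rec <- list(); snaps <- list()
  next_pk <- t_start; next_metric <- t_start
  next_snap <- if (is.finite(cfg$snapshot_dt)) t_start else Inf
  eps <- 1e-12
  prev_expo_t <- NA_real_; prev_expo_v <- NA_real_; cum_expo <- 0

  record <- function(t, A_v, d_v) {
    nv <- state$n; mv <- state$m
    tsel <- nv$values > cfg$tumor_threshold
    isel <- nv$values > cfg$interior_threshold
    avg_ifp <- if (any(tsel) && !is.null(P_field))
      mean(P_field$values[tsel]) else NA_real_
    if (any(isel)) {
      aid <- mean(nv$values[isel])
      aim <- mean(mv$values[isel])
      aix <- if (!is.null(P_field))
        mean(extravasation_coefficient(mv, P_field, cf, cfg$lp, cfg$fp,
                                       clamp = TRUE)$values[isel])
      else NA_real_
      ad <- mean(d_field$values[isel])
    } else {
      aid <- NA_real_; aim <- NA_real_; aix <- NA_real_; ad <- NA_real_
    }
    if (is.finite(ad)) {
      if (is.finite(prev_expo_t))
        cum_expo <<- cum_expo + (t - prev_expo_t) * (prev_expo_v + ad) / 2
      prev_expo_t <<- t; prev_expo_v <<- ad
    }
    rec[[length(rec) + 1L]] <<- data.frame(
      t = t, radius = tumor_radius(nv, cfg$tumor_threshold),
      avg_ifp = avg_ifp, avg_interior_density = aid, avg_interior_m = aim,
      avg_interior_extrav = aix, avg_interior_d = ad,
      cumulative_exposure = cum_expo, plasma_A = A_v, plasma_d = d_v)
  }

  for (step in seq_len(n_steps + 1L)) {
    t <- t_start + (step - 1L) * dt
    last <- step == n_steps + 1L
    th <- t * 24
    A_v <- plasma_concentration(th, aa_events, cfg$ap$t_half_A,
                                cfg$halflife_ln2)
    d_v <- plasma_concentration(th, chemo_events, cfg$lp$t_half_d,
                                cfg$halflife_ln2)
    dosing <- (A_v > eps) || (d_v > eps)
    refresh <- (dosing && t >= next_pk - 1e-9) ||
      (t >= next_metric - 1e-9) || last || is.null(P_field)
    if (refresh) {
      cf <- effective_conductivities(state$n, state$m, cfg$fp,
                                     n_tum = cfg$tumor_threshold)
      P_field <- solve_ifp(state$m, cf, cfg$fp, bcP)
      A_field <- if (A_v > eps)
        solve_agent(A_v, state$m, state$n, cf, cfg$ap, P_field) else zero
      d_field <- if (d_v > eps)
        solve_liposome(d_v, state$m, state$n, P_field, cf, cfg$lp,
                       cfg$gp, cfg$fp) else zero
      mx <- max(d_field$values)
      if (mx > d_running_max) d_running_max <- mx
      record(t, A_v, d_v)
      if (dosing && t >= next_pk - 1e-9)
        next_pk <- t + cfg$pk_dt
      if (t >= next_metric - 1e-9) next_metric <- t + cfg$metric_dt
    }
    if (t >= next_snap - 1e-9) {
      snaps[[sprintf("t%08.3f", t)]] <-
        list(t = t, n = state$n, m = state$m, P = P_field,
             A = A_field, d = d_field)
      next_snap <- t + cfg$snapshot_dt
    }
    if (last) break
    step_dt <- min(dt, t_stop - t)
    state <- step_growth(state, list(A = A_field, d = d_field), cfg$gp,
                         step_dt,
                         inhibition_variant = cfg$inhibition_variant,
                         keep_kill = cfg$keep_kill,
                         d_max = if (cfg$inhibition_variant) {
                           if (!is.na(cfg$gp$d_max)) cfg$gp$d_max
                           else max(d_running_max, eps)
                         } else NULL)
    if (!all(is.finite(state$n$values)) || !all(is.finite(state$m$values)))
      stop(sprintf("simulation became unstable at day %.3f; reduce dt", t))
  }
  structure(list(metrics = do.call(rbind, rec), snapshots = snaps,
                 state = state, d_running_max = d_running_max,
                 config = cfg),
            class = "an_sim_result")
}

#' @export
print.an_sim_result <- function(x, ...) {
  met <- x$metrics
  cat(sprintf(paste0("<an_sim_result: %d metric samples, day %.2f..%.2f, ",
                     "final radius %.3f cm>\n"),
              nrow(met), min(met$t), max(met$t), utils::tail(met$radius, 1)))
  invisible(x)
}

#' Calibrate the antiangiogenic dose to a target MVD reduction
#'
#' Bisection on the first-pulse peak plasma concentration until the
#' microvascular density inside the tumor has dropped by `target` (default
#' 50 percent) at the end of the administrations, relative to the start of
#' the first administration. Monotonicity of the reduction in the dose is
#' verified as the bisection proceeds.
#'
#' @param cfg An `an_sim_config` whose regimen contains antiangiogenic
#'   events.
#' @param target Target fractional MVD reduction.
#' @param tol Tolerance on the achieved reduction.
#' @param upper Upper bound of the dose bracket.
#' @param max_iter Bisection iteration cap.
#' @return List: `aa_peak` (calibrated), `reduction` (achieved),
#'   `evaluations` (dose/reduction table), `baseline_state`, `t_first`.
#' @export
calibrate_aa_dose <- function(cfg, target = 0.5, tol = 0.02, upper = 1,
                              max_iter = 30) {
  if (is.null(cfg$regimen)) stop("config has no regimen")
  aa_days <- regimen_days(cfg$regimen, "antiangiogenic")
  if (length(aa_days) == 0) stop("regimen contains no antiangiogenic events")
  if (target == 0) return(list(aa_peak = 0, reduction = 0))
  t_first <- min(aa_days)
  t_meas <- min(max(aa_days) + 2, cfg$t_end)
  ctrl <- cfg; ctrl$regimen <- NULL; ctrl$snapshot_dt <- Inf
  base <- run_simulation(ctrl, t_stop = t_first)
  mask0 <- base$state$n$values > cfg$tumor_threshold
  if (!any(mask0)) stop("no tumor present at first administration")
  mvd0 <- mean(base$state$m$values[mask0])
  ## reduction measured on the tumor mask frozen at first administration,
  ## so continued growth of the rim does not confound the dose response
  evalf <- function(peak) {
    trial <- cfg
    trial$regimen <- rescale_aa_peak(cfg$regimen, peak)
    trial$snapshot_dt <- Inf
    res <- run_simulation(trial, init_state = base$state,
                          t_start = t_first, t_stop = t_meas)
    1 - mean(res$state$m$values[mask0]) / mvd0
  }
  evals <- data.frame(peak = numeric(0), reduction = numeric(0))
  note <- function(p, r) evals[nrow(evals) + 1L, ] <<- c(p, r)
  lo <- 0; flo <- 0
  hi <- upper; fhi <- evalf(hi); note(hi, fhi)
  if (fhi < target - tol)
    stop(sprintf(paste0("target MVD reduction %.2f unreachable: dose %.3g ",
                        "achieves only %.3f"), target, upper, fhi))
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- evalf(mid); note(mid, fm)
    if (fm < flo - 0.05 || fm > fhi + 0.05)
      warning("MVD reduction not monotone in dose near peak = ", mid)
    if (abs(fm - target) <= tol) {
      return(list(aa_peak = mid, reduction = fm, evaluations = evals,
                  baseline_state = base$state, t_first = t_first))
    }
    if (fm < target) { lo <- mid; flo <- fm } else { hi <- mid; fhi <- fm }
  }
  stop(sprintf(paste0("dose calibration did not converge in %d iterations; ",
                      "bracket [%.4g, %.4g], reductions [%.3f, %.3f]"),
               max_iter, lo, hi, flo, fhi))
}

#' Calibrate the growth rate to a target day-30 radius
#'
#' Bisection on the logistic growth rate `r` of a control (untreated) run
#' until the tumor-edge radius (`n > 0.1` contour) at `target_day` matches
#' `target_radius`. The tumor front is a pulled reaction-diffusion wave, so
#' the radius is monotone non-decreasing in `r`.
#'
#' @param cfg An `an_sim_config` (regimen ignored).
#' @param target_radius Target radius, cm.
#' @param target_day Day of measurement.
#' @param tol Radius tolerance, cm.
#' @param r_range Bisection bracket for `r`, 1/day.
#' @param max_iter Iteration cap.
#' @return List: `r` (calibrated), `radius` (achieved), `evaluations`.
#' @export
calibrate_growth <- function(cfg, target_radius = 1.35, target_day = 30,
                             tol = 0.05, r_range = c(0.02, 2),
                             max_iter = 30) {
  ctrl <- cfg; ctrl$regimen <- NULL; ctrl$snapshot_dt <- Inf
  radius_for <- function(r) {
    ctrl$gp$r <- r
    res <- run_simulation(ctrl, t_stop = target_day)
    utils::tail(res$metrics$radius, 1)
  }
  evals <- data.frame(r = numeric(0), radius = numeric(0))
  note <- function(r, rad) evals[nrow(evals) + 1L, ] <<- c(r, rad)
  lo <- r_range[1]; hi <- r_range[2]
  flo <- radius_for(lo); note(lo, flo)
  if (flo >= target_radius - tol) {
    if (abs(flo - target_radius) <= tol)
      return(list(r = lo, radius = flo, evaluations = evals))
    stop("even the smallest growth rate overshoots the target radius")
  }
  fhi <- radius_for(hi); note(hi, fhi)
  if (fhi < target_radius - tol)
    stop(sprintf("target radius %.2f cm unreachable: r = %.3g reaches %.3f",
                 target_radius, hi, fhi))
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- radius_for(mid); note(mid, fm)
    if (abs(fm - target_radius) <= tol)
      return(list(r = mid, radius = fm, evaluations = evals))
    if (fm < target_radius) lo <- mid else hi <- mid
  }
  stop("growth calibration did not converge; see evaluations")
}
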