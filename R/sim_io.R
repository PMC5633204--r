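## Configuration I/O (JSON), plain-text snapshot store and test fixtures.
## JSON is the canonical config format here: self-describing, ships with the
## installed stack, and round-trips numbers at full precision via %.17g.

an_config_keys <- c("nx", "ny", "extent", "seed", "t_end", "dt", "pk_dt",
                    "metric_dt", "snapshot_dt", "radius0", "relax_time",
                    "inhibition_variant", "keep_kill", "halflife_ln2",
                    "boundary_literal", "interior_threshold",
                    "tumor_threshold", "growth", "fluid", "agent",
                    "liposome", "regimen")

#' Load a simulation configuration from JSON
#'
#' Any key may be omitted; defaults are the package defaults (reference
#' tumor/normal transport parameters, default growth constants). Parameter
#' blocks live under `growth`, `fluid`, `agent`, `liposome`; a regimen under
#' `regimen` with fields `label`, and optionally `chemo_days`,
#' `aa_start_day`, `aa_pulses`, `aa_peak`, `chemo_peak`, `taper_factor`.
#' Derived quantities (`lambda_b`, `P_eff`, `sigma_d`) are always computed,
#' never read. Unknown keys are an error.
#'
#' @param path Path to a JSON file.
#' @return An `an_sim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  raw <- if (nzchar(trimws(txt))) jsonlite::fromJSON(txt) else list()
  config_from_list(raw)
}

#' @rdname load_config
#' @param raw A named list with the same structure as the JSON file.
#' @export
config_from_list <- function(raw) {
  unknown <- setdiff(names(raw), an_config_keys)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  block <- function(name, ctor) {
    args <- raw[[name]]
    if (is.null(args)) return(ctor())
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad) > 0)
      stop("unknown keys in '", name, "' block: ", paste(bad, collapse = ", "))
    do.call(ctor, args)
  }
  gp <- block("growth", growth_params)
  fp <- block("fluid", fluid_params)
  ap <- block("agent", agent_params)
  lp <- block("liposome", liposome_params)
  regimen <- NULL
  if (!is.null(raw$regimen)) {
    rg <- raw$regimen
    bad <- setdiff(names(rg), names(formals(build_regimen)))
    if (length(bad) > 0)
      stop("unknown keys in 'regimen' block: ", paste(bad, collapse = ", "))
    regimen <- do.call(build_regimen, rg)
  }
  top <- raw[setdiff(names(raw),
                     c("growth", "fluid", "agent", "liposome", "regimen"))]
  do.call(sim_config, c(top, list(gp = gp, fp = fp, ap = ap, lp = lp,
                                  regimen = regimen)))
}

#' Dump a configuration to JSON
#'
#' Writes only the primitive inputs (derived quantities are recomputed on
#' load). `dump_config(load_config(p))` is the identity on configurations.
#'
#' @param cfg An `an_sim_config`.
#' @param path Output path; `NULL` returns the JSON string.
#' @export
dump_config <- function(cfg, path = NULL) {
  drop_derived <- function(p, ctor) {
    p <- unclass(p)[intersect(names(p), names(formals(ctor)))]
    p
  }
  out <- list(
    nx = cfg$nx, ny = cfg$ny, extent = cfg$extent, seed = cfg$seed,
    t_end = cfg$t_end, dt = cfg$dt, pk_dt = cfg$pk_dt,
    metric_dt = cfg$metric_dt, snapshot_dt = cfg$snapshot_dt,
    radius0 = cfg$radius0, relax_time = cfg$relax_time,
    inhibition_variant = cfg$inhibition_variant, keep_kill = cfg$keep_kill,
    halflife_ln2 = cfg$halflife_ln2,
    boundary_literal = cfg$boundary_literal,
    interior_threshold = cfg$interior_threshold,
    tumor_threshold = cfg$tumor_threshold,
    growth = drop_derived(cfg$gp, growth_params),
    fluid = drop_derived(cfg$fp, fluid_params),
    agent = drop_derived(cfg$ap, agent_params),
    liposome = drop_derived(cfg$lp, liposome_params))
  if (!is.null(cfg$regimen)) {
    rg <- cfg$regimen
    out$regimen <- list(label = rg$label, aa_peak = rg$aa_peak,
                        chemo_peak = rg$chemo_peak,
                        taper_factor = rg$taper_factor)
  }
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

## ---- plain-text snapshot store ------------------------------------------
## One directory per store; meta.json holds the schema version and grid,
## each snapshot is a set of <name>.csv matrices written at %.17g so that
## float64 payloads round-trip bit-exactly.

an_snapshot_schema <- 1L

write_matrix_txt <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(mat, 2, function(col)
    paste(sprintf("%.17g", col), collapse = ",")), con)
  invisible(path)
}

read_matrix_txt <- function(path, nx) {
  lines <- readLines(path)
  vals <- lapply(lines, function(l) as.numeric(strsplit(l, ",")[[1]]))
  matrix(unlist(vals), nrow = nx)
}

#' Write simulation snapshots to a plain-text store
#'
#' Each snapshot becomes a subdirectory of per-field CSV matrices plus a
#' JSON sidecar; float64 values round-trip bit-exactly (written as %.17g).
#'
#' @param result An `an_sim_result` (with snapshots) or a named list of
#'   field lists.
#' @param path Store directory (created).
#' @export
write_snapshots <- function(result, path) {
  snaps <- if (inherits(result, "an_sim_result")) result$snapshots else result
  if (length(snaps) == 0) stop("no snapshots to write")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  g <- NULL
  for (nm in names(snaps)) {
    sn <- snaps[[nm]]
    sub <- file.path(path, nm)
    dir.create(sub, showWarnings = FALSE)
    for (fn in setdiff(names(sn), "t")) {
      f <- sn[[fn]]
      if (is.null(f)) next
      g <- f$grid
      write_matrix_txt(f$values, file.path(sub, paste0(fn, ".csv")))
    }
    writeLines(jsonlite::toJSON(list(t = sn$t,
                                     fields = setdiff(names(sn), "t")),
                                auto_unbox = TRUE, digits = NA),
               file.path(sub, "snapshot.json"))
  }
  meta <- list(schema = an_snapshot_schema, nx = g$nx, ny = g$ny, h = g$h,
               origin = g$origin)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(path, "meta.json"))
  invisible(path)
}

#' Read a snapshot store
#'
#' @param path Store directory written by [write_snapshots()].
#' @return Named list of snapshots (`t` plus `an_field`s).
#' @export
read_snapshots <- function(path) {
  mfile <- file.path(path, "meta.json")
  if (!file.exists(mfile)) stop("not a snapshot store: ", path)
  meta <- jsonlite::fromJSON(readLines(mfile))
  if (meta$schema != an_snapshot_schema)
    stop("snapshot schema version ", meta$schema, " not supported")
  g <- grid_2d(meta$nx, meta$ny, h = meta$h, origin = meta$origin)
  out <- list()
  for (sub in sort(list.dirs(path, recursive = FALSE))) {
    sj <- jsonlite::fromJSON(readLines(file.path(sub, "snapshot.json")))
    sn <- list(t = sj$t)
    units <- c(n = "dimensionless", m = "dimensionless", P = "mmHg",
               A = "concentration", d = "concentration")
    for (fn in sj$fields) {
      fpath <- file.path(sub, paste0(fn, ".csv"))
      if (!file.exists(fpath)) next
      u <- if (fn %in% names(units)) units[[fn]] else "dimensionless"
      sn[[fn]] <- scalar_field(g, read_matrix_txt(fpath, meta$nx), unit = u)
    }
    out[[basename(sub)]] <- sn
  }
  out
}

#' Write the per-step metrics of a result as tidy CSV
#'
#' @param result An `an_sim_result`.
#' @param path Output CSV path.
#' @export
write_metrics_csv <- function(result, path) {
  utils::write.csv(result$metrics, path, row.names = FALSE)
  invisible(path)
}

#' Deterministic test fixtures
#'
#' Canned scenarios used by the test-suite and examples:
#' * `uniform_vessels` — `m = 1`, `n = 0` on a small grid (IFP sanity).
#' * `disc_tumor` — sharp disc of leaky-wall coefficients in normal tissue,
#'   `m = 1`, coefficient fields built with sub-cell area weighting so the
#'   2-D solve can be compared against the radial analytic oracle.
#' * `grown_tumor_small` — a 64x64 configuration ready for scheduler tests.
#'
#' @param kind Fixture name.
#' @param seed Integer seed.
#' @param nx Grid size override.
#' @param extent Domain edge, cm.
#' @param R Disc radius for `disc_tumor`, cm.
#' @param fp Fluid parameters.
#' @return A list; contents depend on `kind` (always includes `grid`, and a
#'   `config` where applicable).
#' @export
make_fixture <- function(kind = c("uniform_vessels", "disc_tumor",
                                  "grown_tumor_small"),
                         seed = 1L, nx = NULL, extent = NULL, R = 0.5,
                         fp = fluid_params()) {
  kind <- match.arg(kind)
  if (kind == "uniform_vessels") {
    nx <- if (is.null(nx)) 21L else nx
    extent <- if (is.null(extent)) 1 else extent
    g <- grid_2d(nx, nx, h = extent / (nx - 1))
    return(list(grid = g,
                n = scalar_field(g, 0),
                m = scalar_field(g, 1),
                fp = fp))
  }
  if (kind == "disc_tumor") {
    nx <- if (is.null(nx)) 151L else nx
    extent <- if (is.null(extent)) 2 else extent
    g <- grid_2d(nx, nx, h = extent / (nx - 1))
    ctr <- g$origin + grid_extent(g) / 2
    frac <- disc_area_fraction(g, ctr, R)
    lb <- (1 - frac) * fp$lambda_b_normal + frac * fp$lambda_b_tumor
    ## homogenize the Starling source product lambda_b * (P_v - osmotic)
    ## itself (not its factors): the cell-averaged source is what a sharp
    ## interface induces, and keeps the interface error at second order
    src <- (1 - frac) * fp$lambda_b_normal * (fp$P_v - fp$osmotic_normal) +
      frac * fp$lambda_b_tumor * (fp$P_v - fp$osmotic_tumor)
    cf <- structure(list(
      lambda_b = scalar_field(g, lb, unit = "1/mmHg.s"),
      lambda_l = scalar_field(g, (1 - frac) * fp$lambda_l_normal,
                              unit = "1/mmHg.s"),
      osmotic = scalar_field(g, fp$P_v - src / lb, unit = "mmHg"),
      ramp_w = scalar_field(g, frac), delta = 0.1, n_tum = 0.1),
      class = "an_conductivities")
    co <- grid_coords(g)
    rr <- sqrt((co$x - ctr[1])^2 + (co$y - ctr[2])^2)
    return(list(grid = g, m = scalar_field(g, 1), cf = cf, fp = fp,
                center = ctr, R = R, radii = rr))
  }
  # grown_tumor_small: coarse, fast configuration for scheduler tests.
  # 2.4 cm domain so the front stays resolved at 64x64 (h ~ half the front
  # width) and a 0.15 cm seed so the tumor is ~1 cm by the treatment window.
  sim_config(nx = 64, extent = 2.4, seed = seed, dt = 0.025,
             radius0 = 0.15, metric_dt = 1, t_end = 31.5)
}

## exact-ish area fraction of each grid cell inside the disc, by 4x4
## sub-sampling; keeps the discrete interface centred on the true circle
disc_area_fraction <- function(g, center, R, sub = 4L) {
  co <- grid_coords(g)
  off <- (seq_len(sub) - 0.5) / sub - 0.5
  frac <- matrix(0, g$nx, g$ny)
  for (ox in off) for (oy in off) {
    frac <- frac + ((co$x + ox * g$h - center[1])^2 +
                      (co$y + oy * g$h - center[2])^2 <= R^2)
  }
  frac / sub^2
}
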