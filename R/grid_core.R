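#' Uniform 2-D computational grid
#'
#' Node-centered rectangular lattice with uniform spacing. Coordinates are in
#' centimetres; node `(i, j)` sits at `origin + (i-1, j-1) * h`. The grid
#' carries the geometry for all finite-difference operators in the package.
#'
#' @param nx,ny Node counts along x and y (each at least 3).
#' @param h Node spacing in cm (positive).
#' @param origin Physical coordinate of node (1,1), numeric length-2, cm.
#' @return An object of class `an_grid` with fields `nx`, `ny`, `h`, `origin`.
#' @examples
#' g <- grid_2d(11, 11, h = 0.1)
#' grid_extent(g)  # 1 cm x 1 cm
#' @export
grid_2d <- function(nx, ny = nx, h, origin = c(0, 0)) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 3L || ny < 3L) stop("grid needs nx, ny >= 3, got ", nx, "x", ny)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("grid spacing h must be a single positive number")
  if (length(origin) != 2L || !all(is.finite(origin)))
    stop("origin must be two finite coordinates (cm)")
  structure(list(nx = nx, ny = ny, h = h, origin = as.numeric(origin)),
            class = "an_grid")
}

#' @rdname grid_2d
#' @param g An `an_grid`.
#' @return `grid_extent`: physical extent `((nx-1) h, (ny-1) h)` in cm.
#' @export
grid_extent <- function(g) c((g$nx - 1L) * g$h, (g$ny - 1L) * g$h)

#' Node coordinate matrices
#'
#' @param g An `an_grid`.
#' @return List with matrices `x` and `y` (nx-by-ny) of node coordinates (cm).
#' @export
grid_coords <- function(g) {
  x <- matrix(g$origin[1] + (seq_len(g$nx) - 1) * g$h, g$nx, g$ny)
  y <- matrix(g$origin[2] + (seq_len(g$ny) - 1) * g$h, g$nx, g$ny,
              byrow = TRUE)
  list(x = x, y = y)
}

#' @export
print.an_grid <- function(x, ...) {
  ext <- grid_extent(x)
  cat(sprintf("<an_grid %dx%d, h = %g cm, extent %g x %g cm>\n",
              x$nx, x$ny, x$h, ext[1], ext[2]))
  invisible(x)
}

## Unit tags carried by scalar fields. Purely descriptive: operators combine
## them loosely (e.g. laplacian yields "<unit>/cm^2").
.an_units <- c("dimensionless", "mmHg", "cm/s", "1/s", "concentration",
               "1/mmHg.s", "1/day", "cm")

#' Scalar field on a grid
#'
#' One real value per node plus a unit tag. `values` may be given as a matrix
#' (nx-by-ny) or a single number (replicated).
#'
#' @param grid An `an_grid`.
#' @param values Matrix of node values, or a scalar.
#' @param unit Unit tag (free-form string; common tags: "dimensionless",
#'   "mmHg", "cm/s", "1/s", "concentration").
#' @return An object of class `an_field`.
#' @export
scalar_field <- function(grid, values = 0, unit = "dimensionless") {
  stopifnot(inherits(grid, "an_grid"))
  if (length(values) == 1L) values <- matrix(values, grid$nx, grid$ny)
  if (!is.matrix(values) || nrow(values) != grid$nx || ncol(values) != grid$ny)
    stop("values must be a ", grid$nx, "x", grid$ny,
         " matrix matching the grid")
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values, unit = as.character(unit)),
            class = "an_field")
}

#' @export
print.an_field <- function(x, ...) {
  cat(sprintf("<an_field %dx%d [%s], range [%g, %g]>\n",
              x$grid$nx, x$grid$ny, x$unit,
              min(x$values), max(x$values)))
  invisible(x)
}

field_like <- function(f, values, unit = f$unit) {
  scalar_field(f$grid, values, unit)
}

check_same_grid <- function(...) {
  fs <- list(...)
  g <- fs[[1]]$grid
  for (f in fs[-1]) {
    if (f$grid$nx != g$nx || f$grid$ny != g$ny || f$grid$h != g$h)
      stop("fields live on different grids")
  }
  invisible(g)
}

check_finite_field <- function(f, name = "field") {
  bad <- which(!is.finite(f$values), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("%s has non-finite value at node (%d, %d)",
                 name, bad[1, 1], bad[1, 2]))
  invisible(f)
}

#' Boundary condition for finite-difference operators
#'
#' Ghost-node closure used by the discrete operators. `no_flux` seals the
#' domain: the second-difference operators use the conservative closure
#' (zero flux through boundary faces) and the gradient uses the mirror
#' closure (zero centred normal derivative at boundary nodes). `dirichlet`
#' places a fixed value in the ghost node.
#'
#' @param kind `"no_flux"` or `"dirichlet"`.
#' @param value Ghost value for `dirichlet` (finite).
#' @return An object of class `an_bc`.
#' @export
boundary_condition <- function(kind = c("no_flux", "dirichlet"), value = 0) {
  kind <- match.arg(kind)
  if (!is.finite(value)) stop("boundary value must be finite")
  structure(list(kind = kind, value = as.numeric(value)), class = "an_bc")
}

#' @rdname boundary_condition
#' @export
bc_no_flux <- function() boundary_condition("no_flux")

#' @rdname boundary_condition
#' @export
bc_dirichlet <- function(value) boundary_condition("dirichlet", value)

## Pad a value matrix with one ring of ghost nodes according to the bc.
## Two no-flux ghost styles:
##  * "face": ghost repeats the boundary node, so the flux through the
##    boundary face is exactly zero — the conservative closure used by the
##    second-difference operators (and matched by the sparse assemblies);
##  * "node": ghost mirrors the first interior neighbour across the boundary
##    node, so the centred normal derivative at the boundary vanishes — used
##    by the gradient.
pad_ghost <- function(v, bc, style = c("face", "node")) {
  style <- match.arg(style)
  nx <- nrow(v); ny <- ncol(v)
  p <- matrix(if (bc$kind == "dirichlet") bc$value else 0,
              nx + 2L, ny + 2L)
  p[2:(nx + 1L), 2:(ny + 1L)] <- v
  if (bc$kind == "no_flux") {
    s <- if (style == "node") 2L else 1L
    p[1L, 2:(ny + 1L)] <- v[s, ]
    p[nx + 2L, 2:(ny + 1L)] <- v[nx + 1L - s, ]
    p[2:(nx + 1L), 1L] <- v[, s]
    p[2:(nx + 1L), ny + 2L] <- v[, ny + 1L - s]
    p[1L, 1L] <- v[s, s]; p[1L, ny + 2L] <- v[s, ny + 1L - s]
    p[nx + 2L, 1L] <- v[nx + 1L - s, s]
    p[nx + 2L, ny + 2L] <- v[nx + 1L - s, ny + 1L - s]
  }
  p
}

#' Five-point Laplacian
#'
#' Standard second-order stencil; boundary closure through ghost nodes from
#' `bc`. Result has units of `f` per cm squared.
#'
#' @param f An `an_field`, finite everywhere.
#' @param bc An `an_bc`.
#' @return An `an_field` with the discrete Laplacian.
#' @export
laplacian <- function(f, bc = bc_no_flux()) {
  check_finite_field(f, "laplacian input")
  v <- f$values
  nx <- nrow(v); ny <- ncol(v)
  p <- pad_ghost(v, bc, style = "face")
  i <- 2:(nx + 1L); j <- 2:(ny + 1L)
  lap <- (p[i - 1L, j] + p[i + 1L, j] + p[i, j - 1L] + p[i, j + 1L] -
            4 * v) / f$grid$h^2
  field_like(f, lap, unit = paste0(f$unit, "/cm^2"))
}

#' Conservative divergence of a coefficient-weighted gradient
#'
#' Flux-form discretization of `div(coef * grad f)`: the coefficient on each
#' cell face is the arithmetic mean of the two adjacent nodes, fluxes are
#' differenced per node. With a `no_flux` closure the operator conserves the
#' discrete integral exactly.
#'
#' @param coef An `an_field` with nonnegative values.
#' @param f An `an_field` on the same grid.
#' @param bc Boundary condition applied to `f` (the coefficient is mirrored).
#' @return An `an_field`.
#' @export
div_coef_grad <- function(coef, f, bc = bc_no_flux()) {
  check_same_grid(coef, f)
  check_finite_field(f, "div_coef_grad input")
  if (any(coef$values < 0))
    stop("div_coef_grad: coefficient field has negative values")
  h <- f$grid$h
  v <- f$values
  nx <- nrow(v); ny <- ncol(v)
  pf <- pad_ghost(v, bc, style = "face")
  pc <- pad_ghost(coef$values, bc_no_flux(), style = "face")
  i <- 2:(nx + 1L); j <- 2:(ny + 1L)
  ce <- 0.5 * (pc[i + 1L, j] + pc[i, j])
  cw <- 0.5 * (pc[i - 1L, j] + pc[i, j])
  cn <- 0.5 * (pc[i, j + 1L] + pc[i, j])
  cs <- 0.5 * (pc[i, j - 1L] + pc[i, j])
  div <- (ce * (pf[i + 1L, j] - v) - cw * (v - pf[i - 1L, j]) +
            cn * (pf[i, j + 1L] - v) - cs * (v - pf[i, j - 1L])) / h^2
  field_like(f, div)
}

#' Centred gradient
#'
#' Central differences at every node using the ghost closure; with `no_flux`
#' the boundary-normal component is zero, with `dirichlet` the ghost value
#' enters the centred difference.
#'
#' @param f An `an_field`.
#' @param bc An `an_bc`.
#' @return List of two `an_field`s: `dx` and `dy`.
#' @export
gradient <- function(f, bc = bc_no_flux()) {
  check_finite_field(f, "gradient input")
  v <- f$values
  nx <- nrow(v); ny <- ncol(v)
  p <- pad_ghost(v, bc, style = "node")
  i <- 2:(nx + 1L); j <- 2:(ny + 1L)
  gx <- (p[i + 1L, j] - p[i - 1L, j]) / (2 * f$grid$h)
  gy <- (p[i, j + 1L] - p[i, j - 1L]) / (2 * f$grid$h)
  list(dx = field_like(f, gx, unit = paste0(f$unit, "/cm")),
       dy = field_like(f, gy, unit = paste0(f$unit, "/cm")))
}

#' Export a field as tidy CSV (x, y, value)
#'
#' @param f An `an_field`.
#' @param path Output file path.
#' @export
field_to_csv <- function(f, path) {
  co <- grid_coords(f$grid)
  df <- data.frame(x = as.vector(co$x), y = as.vector(co$y),
                   value = as.vector(f$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
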