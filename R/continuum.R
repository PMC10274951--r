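# Reaction-diffusion fields on a uniform cubic lattice, advanced by the
# explicit forward-time centered-space (FTCS) scheme:
#
#   u' = (1 - lam*dt) u + D*dt/h^2 * (6-point Laplacian)
#        + dt (1 - u) A+  -  dt u A-
#
# Sources enter with prefactor (1 - u) and sinks with prefactor u, which
# keeps concentrations in [0, 1] under the positivity time-step condition
# (see the methods vignette). Boundaries are zero-flux Neumann (flux-form
# ghost nodes equal to the boundary node, so the lattice sum is conserved)
# or constant-value Dirichlet.

SUBSTANCES <- c("nutrients", "vegf", "dox", "tra")

#' Construct a substance grid
#'
#' One scalar concentration field on a uniform cubic lattice of `n` nodes
#' per axis with spacing `h`, diffusion coefficient `D` (um^2/h), decay
#' constant `lam` (1/h) and a boundary condition. The physical domain is the
#' cube `[origin, origin + (n-1) h]` along each axis.
#'
#' @param name Substance label, e.g. one of `nutrients`, `vegf`, `dox`,
#'   `tra`.
#' @param n Nodes per axis (the lattice is `n x n x n`).
#' @param h Lattice spacing, micrometers.
#' @param D Diffusion coefficient, um^2/h.
#' @param lam Decay constant, 1/h.
#' @param bc `"neumann"` (zero flux) or `"dirichlet"` (constant boundary
#'   value `bc_value`).
#' @param bc_value Boundary concentration for Dirichlet grids.
#' @param init Initial concentration, a scalar in `[0, 1]` or a full
#'   `n^3` array.
#' @param origin Coordinates of the first lattice node.
#' @return An object of class `substance_grid`.
#' @examples
#' g <- substance_grid("nutrients", n = 11, h = 20, D = 50, lam = 0,
#'                     init = 0.5)
#' @export
substance_grid <- function(name, n, h, D, lam = 0,
                           bc = c("neumann", "dirichlet"), bc_value = 0,
                           init = 0, origin = c(0, 0, 0)) {
  bc <- match.arg(bc)
  if (n < 3) abort("substance_grid: need at least 3 nodes per axis")
  if (h <= 0 || D < 0 || lam < 0) {
    abort("substance_grid: h must be positive; D and lam nonnegative")
  }
  u <- if (length(init) == 1) array(init, dim = c(n, n, n)) else {
    stopifnot(all(dim(init) == c(n, n, n)))
    init
  }
  if (any(u < 0 | u > 1)) abort("substance_grid: init must lie in [0, 1]")
  if (bc == "dirichlet") {
    if (bc_value < 0 || bc_value > 1) {
      abort("substance_grid: bc_value must lie in [0, 1]")
    }
    u <- set_boundary(u, bc_value)
  }
  structure(list(name = name, u = u, n = as.integer(n), h = h, D = D,
                 lam = lam, bc = bc, bc_value = bc_value, origin = origin),
            class = "substance_grid")
}

set_boundary <- function(u, value) {
  n <- dim(u)
  u[c(1, n[1]), , ] <- value
  u[, c(1, n[2]), ] <- value
  u[, , c(1, n[3])] <- value
  u
}

#' @export
print.substance_grid <- function(x, ...) {
  cat(sprintf(
    "<substance_grid '%s'> %d^3 nodes, h = %g um, D = %g um^2/h, lam = %g/h, %s bc\n",
    x$name, x$n, x$h, x$D, x$lam, x$bc))
  cat(sprintf("  values in [%.4g, %.4g]\n", min(x$u), max(x$u)))
  invisible(x)
}

#' @export
as.array.substance_grid <- function(x, ...) x$u

#' Largest stable FTCS time step
#'
#' The explicit scheme is stable for `(lam + 12 D / h^2) dt <= 2`; the bound
#' returned is `2 / (lam + 12 D / h^2)`.
#'
#' @param D Diffusion coefficient, um^2/h.
#' @param lam Decay constant, 1/h.
#' @param h Lattice spacing, micrometers.
#' @return Maximum admissible `dt` in hours.
#' @examples
#' max_stable_dt(D = 50, lam = 0, h = 22.5)
#' @export
max_stable_dt <- function(D, lam = 0, h) {
  if (D < 0 || lam < 0 || h <= 0) {
    abort("max_stable_dt: need D, lam >= 0 and h > 0")
  }
  2 / (lam + 12 * D / h^2)
}

#' One FTCS step of a substance grid
#'
#' Advances the field by `dt` hours with the printed single-line update:
#' simultaneous decay, 6-point Laplacian, and agent source/sink terms. The
#' time step must satisfy the stability bound of [max_stable_dt()];
#' violations are fatal and report the bound.
#'
#' @param grid A [substance_grid()].
#' @param A_plus,A_minus Nonnegative source / sink fields (arrays matching
#'   the lattice, 1/h), or `NULL` for none.
#' @param dt Step length, hours.
#' @return The updated `substance_grid`.
#' @export
ftcs_step <- function(grid, A_plus = NULL, A_minus = NULL, dt) {
  stopifnot(inherits(grid, "substance_grid"))
  bound <- max_stable_dt(grid$D, grid$lam, grid$h)
  if (dt > bound * (1 + 1e-12)) {
    abort(sprintf(
      "ftcs_step: dt = %g h violates the stability bound %g h for D = %g, lam = %g, h = %g",
      dt, bound, grid$D, grid$lam, grid$h))
  }
  empty <- numeric(0)
  ap <- if (is.null(A_plus)) empty else as.numeric(A_plus)
  am <- if (is.null(A_minus)) empty else as.numeric(A_minus)
  if (length(ap) && any(ap < 0)) abort("ftcs_step: A_plus must be nonnegative")
  if (length(am) && any(am < 0)) abort("ftcs_step: A_minus must be nonnegative")
  dims <- dim(grid$u)
  grid$u <- cpp_ftcs_step(as.numeric(grid$u), as.integer(dims), grid$h,
                          grid$D, grid$lam, dt, ap, am,
                          if (grid$bc == "dirichlet") 1L else 0L,
                          grid$bc_value)
  dim(grid$u) <- dims
  grid
}

# Nearest-node index per axis; ties are broken toward the lower index.
nearest_index <- function(coord, origin, h, n) {
  v <- (coord - origin) / h
  i <- as.integer(ceiling(v - 0.5)) + 1L  # 1-based
  if (any(i < 1 | i > n)) abort("point outside the lattice domain")
  i
}

# n x 3 matrix of 1-based lattice indices for points (n x 3 matrix)
node_indices <- function(grid, points) {
  points <- rbind(points)
  cbind(nearest_index(points[, 1], grid$origin[1], grid$h, grid$n),
        nearest_index(points[, 2], grid$origin[2], grid$h, grid$n),
        nearest_index(points[, 3], grid$origin[3], grid$h, grid$n))
}

#' Sample a field at arbitrary points
#'
#' Returns the value at the lattice node nearest to each point (ties broken
#' toward the lower index). Points must lie inside the domain.
#'
#' @param grid A [substance_grid()].
#' @param points Numeric 3-vector or n x 3 matrix of coordinates.
#' @return Numeric vector of concentrations.
#' @export
sample_at <- function(grid, points) {
  idx <- node_indices(grid, points)
  grid$u[idx]
}

#' Central-difference gradient at arbitrary points
#'
#' Evaluates the finite-difference gradient at the nearest lattice node:
#' central differences in the interior, one-sided at the boundary.
#'
#' @inheritParams sample_at
#' @return Numeric n x 3 matrix of gradients (per micrometer).
#' @export
gradient_at <- function(grid, points) {
  idx <- node_indices(grid, points)
  n <- grid$n
  h <- grid$h
  u <- grid$u
  g <- matrix(0, nrow(idx), 3)
  for (ax in 1:3) {
    i <- idx[, ax]
    up <- pmin(i + 1L, n)
    dn <- pmax(i - 1L, 1L)
    span <- (up - dn) * h
    hi <- idx; hi[, ax] <- up
    lo <- idx; lo[, ax] <- dn
    g[, ax] <- (u[hi] - u[lo]) / span
  }
  g
}

#' Write / read a field snapshot
#'
#' Plain-text container: a header with the substance name and lattice
#' geometry followed by the values in column-major order, one per line at
#' full double precision. The round trip is exact.
#'
#' @param grid A [substance_grid()].
#' @param path File path.
#' @return `read_field` returns the `substance_grid`; `write_field`
#'   invisibly returns `path`.
#' @export
write_field <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("name", grid$name),
    paste("n", grid$n),
    sprintf("h %.17g", grid$h),
    sprintf("D %.17g", grid$D),
    sprintf("lam %.17g", grid$lam),
    paste("bc", grid$bc),
    sprintf("bc_value %.17g", grid$bc_value),
    sprintf("origin %.17g %.17g %.17g", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    "values"
  ), con)
  writeLines(sprintf("%.17g", as.numeric(grid$u)), con)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  lines <- readLines(path)
  hdr_end <- match("values", lines)
  kv <- strsplit(lines[seq_len(hdr_end - 1)], " ")
  key <- vapply(kv, `[`, character(1), 1)
  val <- lapply(kv, function(x) x[-1])
  names(val) <- key
  n <- as.integer(val$n)
  u <- array(as.numeric(lines[(hdr_end + 1):length(lines)]), dim = c(n, n, n))
  g <- substance_grid(val$name[[1]], n, as.numeric(val$h),
                      as.numeric(val$D), as.numeric(val$lam),
                      bc = val$bc[[1]], bc_value = as.numeric(val$bc_value),
                      origin = as.numeric(val$origin))
  g$u <- u
  g
}
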